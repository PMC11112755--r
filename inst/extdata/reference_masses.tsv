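id	mass
glucose	180.063388
tryptophan	204.089878
kynurenine	208.084792
serotonin	176.095023
cortisol	362.209324
palmitate	256.240230
linoleate	280.240230
citrate	192.027003
urate	168.028426
creatinine	113.058912
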