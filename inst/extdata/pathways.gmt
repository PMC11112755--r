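tryptophan_metabolism	synthetic toy map	tryptophan	kynurenine	serotonin
energy_metabolism	synthetic toy map	glucose	citrate	creatinine
lipid_metabolism	synthetic toy map	palmitate	linoleate	cortisol
purine_metabolism	synthetic toy map	urate
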