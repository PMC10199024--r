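name	formula	adduct	n_carbons	n_subunits
palmitate	C16H32O2	[M-H]-	16	8
stearate	C18H36O2	[M-H]-	18	9
NAA	C6H9NO5	[M-H]-	6	NA
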