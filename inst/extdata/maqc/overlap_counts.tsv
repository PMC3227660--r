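level	brain	cell_lines	common
gene	16818	18431	11654
isoform	28571	32714	7492
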