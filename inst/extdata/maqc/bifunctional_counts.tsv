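item	brain	cell_lines	common
bifunctional_genes	146	185	49
bifunctional_lncrnas	176	217	41
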