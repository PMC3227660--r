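class	brain	cell_lines
INTRON_RETENTION	13	17
NOVEL_BOUNDARY_OR_EXON	79	90
EXON_SKIPPING	84	110
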