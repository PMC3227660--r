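item	brain	cell_lines
genes	16818	18431
transcripts	28571	32714
protein_coding	27524	31641
noncoding	1047	1073
long_ncrna	760	808
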