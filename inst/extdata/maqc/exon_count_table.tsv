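exons	brain	cell_lines
1	1748	1723
2	2281	2429
3	2888	3294
4	3048	3526
5	2943	3410
6+	15663	18332
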