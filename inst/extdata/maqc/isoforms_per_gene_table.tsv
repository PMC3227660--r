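isoforms	brain	cell_lines
1	11048	11697
2	2933	3334
3	1352	1548
4	699	839
5	352	446
6+	434	567
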