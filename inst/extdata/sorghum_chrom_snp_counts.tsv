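chrom	n_markers
1	10189
2	8946
3	8798
4	7162
5	5454
6	6724
7	3950
8	4388
9	4965
10	5689
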