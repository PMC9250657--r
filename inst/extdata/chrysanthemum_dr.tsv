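locus_id	n_6A	n_A_a	n_6a
SNP-5	0.1539	0.6593	0.1868
SNP-130	0.6308	0.3385	0.0308
SNP-406	0.5303	0.3030	0.1667
SNP-558	0.0421	0.3053	0.6526
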