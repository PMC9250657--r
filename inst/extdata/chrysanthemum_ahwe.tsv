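locus_id	n_6A	n_A_a	n_6a
SNP-4	0.4000	0.4875	0.1125
SNP-18	0.5753	0.3699	0.0548
SNP-113	0.7826	0.1884	0.0290
SNP-312	0.8254	0.1587	0.0159
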