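locus_id	n_6A	n_5A1a	n_4A2a	n_3A3a	n_2A4a	n_1A5a	n_6a
EX1	29	21	17	10	10	10	23
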