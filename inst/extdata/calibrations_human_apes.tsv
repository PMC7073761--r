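taxon_a	taxon_b	split_time_myr
human	chimpanzee	6
human	orangutan	16
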