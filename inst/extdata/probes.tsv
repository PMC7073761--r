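probe	coordinates	reported_length_bp
STS1	chr16:10145382-10145806	425
STS2	chr16:10127122-10127552	431
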