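n_false_segments,false_length_bp,chrx_length_bp,n_arrays
17,1045770,144288218,2
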