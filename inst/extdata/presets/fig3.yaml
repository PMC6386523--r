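# integrated model, clone protocol on a 20 x 20 hexagonal patch
variant: integrated
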