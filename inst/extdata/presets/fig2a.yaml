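# single-component EGFR front: bistable kinetics mu/k = 4, n = 3
variant: e_only
eta: 8.0
mu_E: 4.0
k_E: 1.0
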