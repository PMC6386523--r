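# excitable EGFR + L'sc pulse (printed two-component equations, a = 1)
variant: e_l
eta: 1.0
mu_E: 4.0
k_E: 1.0
mu_L: 0.4
k_L: 0.2
hill:
  e_self: {exponent: 3.0, threshold: 1.0}
  l_on_e: {exponent: 3.0, threshold: 1.0}
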