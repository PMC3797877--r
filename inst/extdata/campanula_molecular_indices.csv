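index,estimate,lower,upper
F_prime_RT,0.092,0.080,0.105
F_prime_SR,0.499,0.488,0.510
F_prime_ST,0.591,NA,NA
G_prime_ST,0.539,NA,NA
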