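# case = half-siblings
# r = 1e-08
# b = 1e+07
# source = empirical
# seed = 1912
# states = 0,1
0.839517372766 0.160482627234
0.162167360036 0.837832639964
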