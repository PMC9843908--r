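# case = avuncular
# r = 1e-08
# b = 1e+07
# source = empirical
# seed = 1911
# states = 0,1
0.806999929007 0.193000070993
0.192456664554 0.807543335446
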