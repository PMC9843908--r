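# case = third-degree
# r = 1e-08
# b = 1e+07
# source = empirical
# seed = 1910
# states = 0,1
0.89998987205 0.10001012795
0.298526906504 0.701473093496
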