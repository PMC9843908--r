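# case = fifth-degree
# r = 1e-08
# b = 1e+07
# source = empirical
# seed = 1908
# states = 0,1
0.9713354486391 0.0286645513609
0.420923998739 0.579076001261
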