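# case = fourth-degree
# r = 1e-08
# b = 1e+07
# source = empirical
# seed = 1909
# states = 0,1
0.9484612147728 0.0515387852272
0.358456707044 0.641543292956
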