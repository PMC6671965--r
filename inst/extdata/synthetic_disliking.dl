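dl n=5
format = fullmatrix
labels:
ana,ben,cam,dee,eli
data:
0 0 1 3 0
0 0 2 3 1
0 0 0 2 3
3 2 0 0 0
2 3 1 0 0
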