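# toy identity-like substitution matrix over a reduced alphabet
A R N D C
A 4 -1 -2 -2 0
R -1 5 0 -2 -3
N -2 0 6 1 -3
D -2 -2 1 6 -3
C 0 -3 -3 -3 9
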