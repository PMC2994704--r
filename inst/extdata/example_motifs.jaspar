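>MA_ex1
A [ 12 0 1 11 0 2 ]
C [ 0 11 1 0 1 10 ]
G [ 0 1 10 1 0 0 ]
T [ 0 0 0 0 11 0 ]
>MA_ex2
A [ 3 10 0 0 9 ]
C [ 4 0 1 10 1 ]
G [ 2 1 11 1 1 ]
T [ 3 1 0 1 1 ]
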