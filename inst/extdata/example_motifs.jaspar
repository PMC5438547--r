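>MA0001.1 DEMO_GATA
A [ 0 18  1  0  1 ]
C [ 2  0  0  0 17 ]
G [ 1  2  0 20  1 ]
T [17  0 19  0  1 ]
>MA0002.1 DEMO_PALIN
A [10  0  0  0  0 10 ]
C [ 5 20  0  0  1  5 ]
G [ 5  0 20  1  0  5 ]
T [ 0  0  0 19 19  0 ]
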