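>MA0522.1-like	TCF3_Ebox_synthetic
A  [  800  850  930   10  980    7    7    7   10   23   50   67 ]
C  [   67   50   23  970    7    7  980    7   10   23   50   67 ]
G  [   67   50   23   10    7  980    7    7  970   23   50   67 ]
T  [   67   50   23   10    7    7    7  980   10  930  850  800 ]
>MA0028.2-like	ELK1_ETS_synthetic
A  [  800  850   23   10    7    7  980  980   10   23   50   67 ]
C  [   67   50  930  970    7    7    7    7   10   23   50   67 ]
G  [   67   50   23   10  980  980    7    7  970   23  850   67 ]
T  [   67   50   23   10    7    7    7    7   10  930   50  800 ]

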