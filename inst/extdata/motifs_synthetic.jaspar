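>SYN001 synthetic-AP1-like
A  [  2 18  1  0  1 16  2  3 ]
C  [  3  1  0  1 17  1  2 14 ]
G  [ 13  0  1 18  1  2  1  2 ]
T  [  2  1 18  1  1  1 15  1 ]
>SYN002 synthetic-ETS-like
A  [  1  0 19  0  2  5 ]
C  [  2  1  0  1  2  6 ]
G  [ 16 18  0 18  2  4 ]
T  [  1  1  1  1 14  5 ]
>SYN003 synthetic-forkhead-like
A  [ 14  2  1 16 15  2  9 ]
C  [  2  1  1  1  2  2  4 ]
G  [  2  1  1  1  1  2  3 ]
T  [  2 16 17  2  2 14  4 ]
>SYN004 synthetic-CT-rich
A  [  1  2  1  2  1  2 ]
C  [ 15  2 16  2 15  2 ]
G  [  2  1  2  1  2  1 ]
T  [  2 15  1 15  2 15 ]
>SYN005 synthetic-GC-box
A  [  1  1  2  1  1  2  1 ]
C  [  2 16  2  2 16  2 15 ]
G  [ 16  2 15 16  2 15  3 ]
T  [  1  1  1  1  1  1  1 ]
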