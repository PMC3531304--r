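>SYN_CTCF
A  [   3   4   3   2   2  35   3   2  35   3   2   3   2   4   4   4   4   3  35 ]
C  [   2   2   4  35  36   3  34  35   2   2   4   2   2   2  35   4  36   2   4 ]
G  [   2  35  34   4   2   3   4   3   3  34  36  36  35  36   2  34   2   2   4 ]
T  [  36   2   2   2   2   3   3   3   3   2   2   4   3   4   3   2   3  34   2 ]
>SYN_TATA
A  [   3  36   4  36  36  35  18  19 ]
C  [   2   2   3   3   4   3   2   3 ]
G  [   4   4   3   3   3   3   2  18 ]
T  [  34   3  34   4   2   2  18   3 ]
>SYN_CAAT
A  [   4   3   3   4  34  34   2   4   4 ]
C  [   4   4  34  36   3   3   4  35   2 ]
G  [  34  34   3   2   4   3   3   2   2 ]
T  [   2   4   4   3   3   3  36   2  36 ]
>SYN_GC
A  [   3   2   2   4   3   2   3   4   3   2 ]
C  [   4   4   4   4  36   4   2   3   4  35 ]
G  [  35  36  34  35   4  34  36  35  35   2 ]
T  [   2   4   3   4   3   4   3   3   2   3 ]
>SYN_EBOX
A  [   2  35   3   3   2   2 ]
C  [  36   2  36   4   4   4 ]
G  [   2   3   3  35   2  35 ]
T  [   2   4   3   3  36   3 ]
>SYN_NFKB
A  [   3   3   3  34   2   2   3   3   4   2 ]
C  [   2   2   2   3  36   4   2   2  36  34 ]
G  [  36  36  35   2   2   2   3   3   3   4 ]
T  [   4   3   4   4   4  35  36  35   2   3 ]
>SYN_AP1
A  [   3   2  34   3   4   4  36 ]
C  [   3   2   2  35   3  34   2 ]
G  [   3  36   2   4   2   4   4 ]
T  [  35   3   4   4  34   4   2 ]
>SYN_CREB
A  [   4   4  35   2   4   2   4  35 ]
C  [   2   3   3  35   3   2  34   2 ]
G  [   2  35   2   4  36   4   3   4 ]
T  [  36   4   4   2   4  36   4   4 ]
>SYN_MEF2
A  [   2   4  34  34  34  35  35   2  36   4 ]
C  [  35   4   3   4   4   2   3   3   4   2 ]
G  [   4   2   3   4   4   2   4   3   4  36 ]
T  [   4  34   4   4   4   3   3  35   4   2 ]
>SYN_SRF
A  [   2   3  36   2  36   2   4  34   4   4 ]
C  [  36  35   4   4   3   3   3   3   4   4 ]
G  [   2   2   2   2   4   2   3   3  34  34 ]
T  [   4   3   4  36   4  34  35   4   4   4 ]
>SYN_IRF
A  [  34  34  11   4   4  36  35  36 ]
C  [   2   3  12   2   4   2   3   3 ]
G  [   3   3  11   2  35   4   2   2 ]
T  [   2   4  12  35   3   4   2   2 ]
>SYN_HSE
A  [   4   4   4   2  36   3  35  34 ]
C  [   2   3  36   2   2   3   2   3 ]
G  [   3   2   2   2   4  35   2   2 ]
T  [  35  34   3  36   2   2   3   3 ]
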