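>GRE_SYN GRE
A [ 85  5 85 85  5 85 25 25 25  5  5  5  5  5  5 ]
C [  5  5  5  5 85  5 25 25 25  5  5  5  5 85  5 ]
G [  5 85  5  5  5  5 25 25 25  5 85  5  5  5  5 ]
T [  5  5  5  5  5  5 25 25 25 85  5 85 85  5 85 ]
>RFX_SYN RFX
A [  5  5  5  5  5  5 85  5  5  5  5 85 85  5 ]
C [  5  5  5  5 85 85  5  5  5  5 85  5  5 85 ]
G [ 85  5  5 85  5  5  5  5 85 85  5  5  5  5 ]
T [  5 85 85  5  5  5  5 85  5  5  5  5  5  5 ]
>KLF_SYN KLF
A [  5  5  5  5  5  5  5  5  5  5 ]
C [  5  5  5  5  5  5  5  5  5 85 ]
G [ 85 85 85 85  5 85 85 85 85  5 ]
T [  5  5  5  5 85  5  5  5  5  5 ]
>SP_SYN SP
A [  5  5  5  5  5  5  5  5  5  5 ]
C [  5  5  5  5 85  5  5  5  5 85 ]
G [ 85 85 85 85  5 85 85 85 85  5 ]
T [  5  5  5  5  5  5  5  5  5  5 ]
>ZNF_SYN ZNF
A [  5  5  5  5 85  5  5  5  5  5 ]
C [  5 85  5 85  5  5  5 85  5 85 ]
G [ 85  5 85  5  5  5 85  5 85  5 ]
T [  5  5  5  5  5 85  5  5  5  5 ]
>EGR_SYN EGR
A [  5  5  5  5  5  5  5  5  5  5 ]
C [  5 85  5  5  5  5  5 85  5  5 ]
G [ 85  5 85  5 85 85 85  5 85 85 ]
T [  5  5  5 85  5  5  5  5  5  5 ]
>NR_SYN NR
A [ 85  5  5  5  5 85 85  5  5  5 ]
C [  5  5  5  5 85  5  5  5  5  5 ]
G [  5 85 85  5  5  5  5 85 85  5 ]
T [  5  5  5 85  5  5  5  5  5 85 ]
>STAT_SYN STAT
A [  5  5  5  5  5  5  5 85 85 ]
C [  5  5 85 85 85  5  5  5  5 ]
G [  5  5  5  5  5 85 85  5  5 ]
T [ 85 85  5  5  5  5  5  5  5 ]
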