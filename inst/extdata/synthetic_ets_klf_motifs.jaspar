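# Synthetic count matrices in JASPAR text layout, for examples and tests.
# Cores loosely follow the ETS (GGAA/GGAT) and Krueppel-like (GC-box)
# families; the counts are invented, not measurements.
>SYN_ETS1 synthetic-ets-like
A [  3 42  2  1 45 44  2  8 ]
C [ 40  2  1  2  1  2  3 30 ]
G [  4  3 44 45  2  2 40  6 ]
T [  3  3  3  2  2  2  5  6 ]
>SYN_EHF synthetic-ese-like
A [ 10  2 44  1  1 46 45  3  9 ]
C [ 28  3  2  2  1  1  1  4 29 ]
G [  6 42  2 45 46  1  2 38  6 ]
T [  6  3  2  2  2  2  2  5  6 ]
>SYN_KLF4 synthetic-klf-like
A [  4  2  2 41  3  2  2  3  4 40 ]
C [  6  3  3  3  4 41  3  4  5  4 ]
G [ 36 42 42  3 40  4 42 40 37  3 ]
T [  4  3  3  3  3  3  3  3  4  3 ]
>SYN_FEZF2 synthetic-zf-like
A [ 30  2  3  2 40  2  4 ]
C [  5  3 40  3  3  3  4 ]
G [  8 42  3  2  4  3 36 ]
T [  7  3  4 43  3 42  6 ]
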