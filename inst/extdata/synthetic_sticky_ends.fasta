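>l5_synthetic_standin length=5
CGCGT
>l6_synthetic_standin length=6
ATGCGC
>l7_synthetic_standin length=7
GCACCCC
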