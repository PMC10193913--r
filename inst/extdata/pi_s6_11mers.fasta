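>mTRPV3 S6 pi-region 11-mer offset=662
ILTFVLLLNML
>hTRPV6 S6 pi-region 11-mer offset=563
IIATLLMLNLL
>hTRPM4 S6 pi-region 11-mer offset=1028
LVANILLVNLL
>mTRPM8 S6 pi-region 11-mer offset=964
LSTNILLVNLL
>hTRPC3 S6 pi-region 11-mer offset=728
VTMVVVLLNML
>hTRPA1 S6 pi-region 11-mer offset=945
IFVPIVLMNLL
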