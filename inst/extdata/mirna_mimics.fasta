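>miR-20a
UAAAGUGCUUAUAGUGCAGGUAG
>miR-20a*
ACUGCAUUAUGAGCACUUAAAGU
>miR-34b
UAGGCAGUGUCAUUAGCUGAUUG
>miR-34b*
AUCACUAACUCCACUGCCAUCA
>miR-373
GAAGUGCUUCGAUUUUGGGGUGU
>miR-373*
ACUCAAAAUGGGGGCGCUUUCC
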