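>htel22 human telomeric core
AGGGTTAGGGTTAGGGTTAGGG
>htel23 5'-T extension
TAGGGTTAGGGTTAGGGTTAGGG
>htel24 5'-TT extension
TTAGGGTTAGGGTTAGGGTTAGGG
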