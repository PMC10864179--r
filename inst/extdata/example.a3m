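>query
CFPTPKCMSQCNVAMDKQTSYYMYYLEHYSYDCTTDAGYK
>hom0001 OS=Homo sapiens
DFQTQLCMTQDNWANEKQVSYYMYALEHYTYEDVTDAHYK
>hom0002 OS=Mus musculus
CFPTPKCPVQCNVDMFMQTVYCMYYLEHYSYDCTTFAIYM
>hom0003 OS=Danio rerio
CIPYPNFMSQCRAAQGNTYSYYMYYLHHYSDDCYTGAGDK
>hom0004 OS=Homo sapiens
CKPAPKCRYVGNVFMDKQTSEYMYYLEHYYYDCTADAGYK
>hom0005 OS=Mus musculus
CLVTVKCMSQCNDAMDKQCSFYMYYRKHFAYIHCCDGGFK
>hom0006
CMPTPKCMSYCNEAMKKYTSGGMYYLEHYSGDCTTKAGYR
>hom0007
KFYTYKKVDQKNVIMLKQTSYYVHYLEQYSYDKTEDAPYS
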