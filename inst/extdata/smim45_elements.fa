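>full_silencer
tgcgcgacaacctggccttcggcggcccggaggtctgagccgacttgcaaaggggatagg
cgggcggcaccgggcgccctcccccagcccgccccgcccgcccagcccggagacccccaa
ggcagagggaggccggcctgttggccctccacgctatccctctgcagcctgggccctccc
gacagaggccccaggtgcgctggcagtggaggtggggcacttaggtgcct
>exonic_silencer
tgcgcgacaacctggccttcggcggcccggaggtctga
>silencer_b
gccgacttgcaaaggggataggcgggcggcaccgggcgccctcccccagcccgccccgcc
cgcccagcccggagacccccaaggcagagggaggccggcctgttggccctccacgctatc
cctctgcagcctgggccctcccgacagaggccccaggtgcgctggcagtggaggtggggc
acttaggtgcct
>enhancer1
ctagtggctgaagcaccgcccaggaggaaaaaccggcgggggaagcagggccgcctgcac
ctaccaagatggtggccgtgttcaggccgggcagcttgtccaggggcctcaacaccgaca
tcacagccgcaggaccaaccgttgctcctgcggtgcgcgccgatctttcaaaccgccctg
agtccagcccctagagcgcggcctgggggc
>enhancer2
gagactccgtctcaaaaaaaacaaaccctctgtgaactcacagtcaccccccagtcccac
atatgctggaaaggacctgtcatacctgaagagcccctagatggcgcagaggtgtctgtg
gtgggggacctaggtcctgaagccacctcacccagaggctttccccctgcccatccccag
gtttctgggaacggattccctagggaggtggttcctggaagccttttcccagccacgccc
cgtgggccctagggggctgctctctccctcctgagaatagccctcaacacgtggcagata
ccttgtctatggcatagggggagggggaggatccatgcttgggaaggtggaccccacccc
caacgtcagctcttggctttgaattccagctcagtcactgagaagctgagggctctggga
gaaggagaaggccagcagcatcacctctctgcctcatcccaaaatggggtctcaacacca
atccagctgggaggactgcaggaagtgatgttggggccagctggaagatgggagtgctca
atgcctgtgctggctgtacaccagccaggggtgctgtggggtagatgaggcagaatgggg
agggggagccatttgcaagggtcctgaa
>embedded_silencer
ctagatggcgcagaggtgtctgtggtgggggacctaggtcctgaagccacctcacccaga
>enhancer3
agtttcactcttgttgcccaggctggagtgcagtggcacagtcgtggctcactggaactc
cacctcctgggttcaagcaactctcctgcctcagcctgccgagtagttgggattacaagc
atgtgccaccacacctggctaattttgtacttttagtagagacagggtttcaccatgttg
gtcaggctggtcttgaattcctgacctcaggtgacccatcctccttggcctcccaaagtg
ctgggatcataggcatgagccattggcctggttgcaaaatgctctttaggcattgtcttg
ttaaaactgcaaagtacccaggctgcatgcggtggctcacgcctgtaatcccagcacttt
gggaggccgaggtgggcggatcacgaggtcaggagatcaagaccatcctggctaacacgg
tgaaaccccgtctctactaaaaatacaaaaaattagctgggtgcagtggcggtcacctgc
agtcccagctactcaggaggctgaggcaggag
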