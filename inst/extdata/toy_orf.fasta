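>toy_orf
ATGATCTCAAGTTGGTTCGTACCTTTACCCACAAACCGTACCGTCAACTTTTGCGCGAGA
CTAGACGCAAATTCTCGTACGTCGACGAGATTGAGAAGGACGTGTCTAGTTGATAATTCA
CATAATGTTGCTGAGCGCATCGAACGCGGCGGGAGTTTCATTGACGGCGCAGTCGCAGTT
CCTATAGCACTGCATGTCTTACTTCGGATATGCTTTCGGGGCCGCGGTGAGGGCCTGTTC
ATTAGTGTCTGTGGCTTCAACATATCCGCAAACGGGATGGGGGTTGTGCGAAGACAGCAC
CAAGTGCTAATCTTTCTACCGGTCAGTTCTAGAGGGCTGATGTTGTTAGTTCCCCCGTCA
CTATCAAAGTTGTGGGCTTACCATCAAAGTACGCATTACGTGGATCGGTATCGAGCGCGG
TCGGATATGTACGTCAGGATACCGTATCCCTACGTATGTGAATTTACAACGCGGTGGAGA
ATATTTTTCGTCGACAGCAGTGGTAATTGGGCCTGCCACTGCTCGAGCCGGATATTCTAC
CAGCAAAAGCCCATCGATCACTTGACTTTAGGACAATGCGCTAGGGCGGAAATGTGGCCT
GATCAACAACTCGGGTTTATAGGGAGGGGTACTATTTTGTGTTTTACCATGGAGCGGATT
TGTTGTGTAAGACTTTCATTCCCGTCCGCGCGGAATATACCGGCCACTCTATGCGTGCCA
TCAGAACCAACCCATATCAGTATCAAAAAATACTGCCGCAGCGTAGCAGTGTCCTTTTTG
TTTGTCCTTCCTGAGTCGTCGAAACGGGATATAGGTTCAGGCGATTTTGCTCGCCTTACA
CCAATGGGCGTACGCATCTCAGGAGTATCCGAGGCTGACCATGCTATCAAGAATTATTAA
>flank5
GCAAATCTGTAAGAATGGTCAAGCATCGACCCCTTCGAGTCTCTCACCTACCTGCCAAGT
>flank3
AACCCTCATAATGGCTGAAACGGCAAGCTAGATTACCGCCTCATATCTCGTCCTATTGGG
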