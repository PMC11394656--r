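>miRNA_01
GGCACAGCTTGGGAGACTTT
>miRNA_02
ACCAGCACTATCCATTTCGG
>miRNA_03
CTTATGGTATCCCAACACTGG
>miRNA_04
CGGACGGGCAGATTAAGCCCA
>miRNA_05
AACGTGCCGTCTTTATTTCTT
>miRNA_06
GATGACATTGGCACCGTTGGT
>miRNA_07
GGAATCGTCCCGCTCTGAATG
>miRNA_08
ATCCACGGATCAAGATCGATG
>miRNA_09
ACAAGCTCAACTCAGGGCCCTC
>miRNA_10
GTGTTACCCTCCCTCTGCAGTC
>miRNA_11
CTCTAGTCTCCAAAGCAGCAAA
>miRNA_12
TGGCGCTGCGGCACTCTAGGAG
>miRNA_13
GGCGAACCTGTACTCAAAAGGA
>miRNA_14
AAAGTGCTGATATTGTACAATG
>miRNA_15
GGCACATAGTGCGCAGCAAATC
>miRNA_16
TGTAAGAATGGTCAAGCATCGA
>miRNA_17
CCCCTTCGAGTCTCTCACCTAC
>miRNA_18
CTGCCAAGTAACCCTCATAATG
>miRNA_19
GCTGAAACGGCAAGCTAGATTAC
>miRNA_20
CGCCTCATATCTCGTCCTATTGG
>miRNA_21
GATCGGTCATCTTAGTCACCTCC
>miRNA_22
CGCGCCAAATCGACTCTATTAGT
>miRNA_23
CAACTCCTTTTCAACTGACATGTC
>miRNA_24
GGGTGGACTCGGGTATTTGGTGAC
>rRNA_01
TCCCTCTACAGTCAGGGTGCAGGTGCAAGGATATAGAACCTCCTCAGTTCAGACCGCATCTGCTGACTTCGGGCGATTCGTACGTCTCGCTTATTGCCCAACGCGCTTTGCCTAATGGAGTACTCATTCGCGTCGTTAGTTAGCAAGTATCTGTCCGATGGTAGTAGAGAGTAGCTGACCGGGATCACATTTCCTACCAGCAGGGCACGGGAGATATCATTGAATGAGCAATATACGTCTCCGATGTTTGTCGGAGCGGCCAATTACAACCGCGGAGTGGTAAGCTTTTATTATGAAGTAACCTAAACTATGGGAGGACCAGTCCTTCATCTGGCAAGGAGGCAGCGCGGGAGCAGCGAAATACGCGGGAAACGTCCGTCTGCATCCTAGCGACATTAGA
>rRNA_02
ACTGGATTCTTTGCTAGGCTTGAATGAAGTCGATAGATCTCCAATTTCGATAGACATACCCCCGGTGGGTTCGGAACAATTTGACTGCACTTTTTCTCGTAAGTTGAAAAGGCTCTTAGCGCATGCGGGTTGATTCGCGGCCTACAAAAAAGGTGTGCGGGACCAAAACCAATGGAGCGAAACCACTTGATACCAAGCCATGCAGGTGGGCAACCTTGACCTCTCAACCACAACAGTTTAATGTGGCGGGGGCCGACTGGCGGTATATTAACGCCATGTATGGAGTTGCTGAACCACCCCGCGTAGAGCGTACCTCCGGTTGGTTCTCGTTCTTATTTAGAAATGTGCTTCTGGATGCCCTTCGAGAAATACGTAACCTAATCATACATCAAATTATCGA
>rRNA_03
TAACGCCAGACCTGTAGTGCACTATCTGACTACATGAGGTTGCAGGTAGATTATTGGCATTAATAATACCCCGCTATTCTCCGCTTAAGGACAGCTACCGGCATAATCCTTTAGGCGTTCCTCAAGTAGCGCATTTCACGATGCCCAGGTTTCGCACGAGCGTACTACTATAAGAATGAATCCACGACTAGTTGTCCTCCTCAGTTAGTGAGGAACCTAGAGAGACCTTATAGGCACTGGAATGCCCCTTTTGGCTCTCCGCCGAGGAGGGAACTTGGTTCTCTTCAGATGCTCACCTACAGGTCGTGGTCAGCACGTTCGCTTGATGCGCGTATGCTCCGACGACGGGCTAAGCTGTCTCTCAATGTGCCGGGAGATATATTGACTCACGGAAGTCCAC
>tRNA_01
CCGGCATTGCACTAATAGGAACGCTCGCCAGATTGTTGATAACTGTCCGTGAGGCCGGTCTACAACCGCGGACTCGACTG
>tRNA_02
ATCAGAGTGACCTTCATTAATTAGCAGAACGCATTTGTCTTATGACTGGCTACATATGCCCGGTCGCTACCTGGGTGTCG
>tRNA_03
CGAGGATACTCGCACCAGACAGCTTTCTGGACATGGCCAAAAGAGCTAGCCAAGAAGGAAGGTTTCTCGTTCACAGTGAG
>tRNA_04
CATGCTTATTGGCACAGTCGGGTGGCGTCTTCTCAGTTGCGGCCGCGCACGCTGATTTGTCCAGCAAGGTCTACGCGCTA
>snRNA_01
TAGAACTGACGTGTACAAGGAGGCAACAAAAACGGAGGCGTATATGCCAATCCCGTAGGCCGGGACAGGGACAGCTCGTTTGCGGACTATTTGCATGATCCCTGAGGTTGAAATAAGGTAATTTCGACCAGTTGTGTCGCGCTATAGCTT
>snRNA_02
CGCGGCGGTCTTGCTCTTATGTGGCGTGTGCCTTTTCGTTTGTTTCAGCTTTTTCGCCCAATGGTCGGCGCACCTTAGTCGATACCGGCATATGGCGTGAAATTTTATGAGAGCCTTTTTACCTCCTAATCGGCACTTCAGTGATACAAC
>snRNA_03
GTAAGATCATATGTGAAGAGACTAAGGGAGCCATTTATGTTCGCTAGGCAATGCGAGAGTGCGTGTTGCGCCTAGCTCGGAACGCTTCTTATCCTCATTCCCCCGTGATTGGGTATTACTCGCTCATCCCTAACGAAGGTTCAAGACAAC
>snoRNA_01
TGGTCCGGATGGACTGAAGGGGTTTTGGCGGATAACACTGCAATTTTCCCTATGACAGTGGTTTCACTTGAGCACTCTTAAAGTACGCCATATCTACTGGGCTACTCATTCGGTCGACTTGTTACGTAAT
>snoRNA_02
GGTAGAGAACAGGCTGAACATTCATACTGCTTTACCTCCTCTTTTCGCACGATACTCAGGTTTCAGCTAGTATGAGTTTCGACTGTCCTACCCGGTGTAAAGCTACCATAGTCATCCATTCTCCGTGTCG
>snoRNA_03
GGGCACACCAGCTCAGCCGATGTACGTGCCTATAGATGGAGGCAAGTAGTATGCATACACCCCTCCGACTCCACTGAAGGTCGTCGAGCTGGGCCTTCTACTCTTGCTCGTGCTAATTCCCTTTATCAAC
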