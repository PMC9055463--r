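>Pseudomonas_synthetic_type_strain_16S
GTCCTGTACGATCAGGTACTCTTAACGCCTTACATTACGATTTAAACGTAATAAGTGTATTCACTCATCA
ATCACGCCGACTCGGGGTACCAACAACCTAACCGCATACGTCCTACGGGGATTAATAACCGTACGTTGGA
TACTACAGCCTTGCTTATTCCACAAGCCGCAGATCACGCATCCAAAAATGAGCATATCTTCTTCTTAAGT
AAAAGGTCGGCAAACGTTGTAAGTATGTTTAGTGGGTACTTTCTGGCTCCCTTACGTTGGGTCCACGCCC
TACGACTTTCATATTCCCGCAGGTCCCTGCGGCCTTCTACAATTGGGGTCGTGTGTGAAGAAGGTCTTCG
GCGAATAACTGGGTCCCGAGCGAGTGTGGTAATGCGTTATGGCTCCCTAAATATCGGAGACACGCCCTTT
ATTCGGAGTGTCTTTGGTGTTTAAAGAACGTGATGAGTTATGCCACCATTCAGTATCGAATCAGCTCGCA
AGATTGTTATGGGGCCATTAAGCTCGCTGAATTCACGTCGCCGTATCGGTCGTTGAGCCGCTTATTCCGG
TTGGCCGCCCAGTAAAATCAAACCCTGCTAGTCAGCCGGATGCTGATACTCACTAAGCAAGCTTACATCC
GGTAGTACCACAAACGCTGCGCGTTTCCCTGCCTATAATGCTGGCGCAAGGGATCTCGGTGGACAAATTA
GGTGGCGAGACGAACCCAGGTAGTGCGTCGCGCGACACTACGTCAACGATGTCTCCCCGCAAAATTTGAG
ACGAACAGTCATGAGGATAGGGGATGACACATTACATCATGGTGAATACCGGTGCACCTTAGGGCGCTAT
TATCAAAGCATTTTATAACAATGGCGCAATTTACGTGATGTCCGTCGAATCTTTAGTACGGTCCCTCTTG
GTGGGCTTACCGCTAAATGGGTCAGCCGCGAGTCATGATCCCTATAGATCTCAGCTCTCGCCCCCTAATA
GACCTATAATCAAACAACAT
>Colwellia_synthetic_type_strain_16S
GAGCCCTACCGTGCCTCTCGTCTGCCGAAGCAACCTACGGGAGAAGAATAGGAGGAGCTACCAGATGTGT
ACACCGCTCCTCGGCTCTTTACATTAACTCATACGAGGGGTGCAAGCGTCGAAACGGTGGTTCAATCCTC
CCGAACTAAACCTCACATGCTTTTTGACAAATGAATGCTCGGCTTTCTTACGTAGTTTCCCTCGTTTCCT
GGATTCGATCACGGGGTACACGAGTCAGCCACCCGGGAACACCTGCGGGCGACCTGCGTAGAGATTGGAA
GGAACATCAACGAGGTGTCACACCAGAAGAGTGCATTAGCCCAGCAGTAGAGTCCGTCTCTATGACCTAT
CCTGGTCACATGCTTCCTGCTTAACTCAAGAGTATCTTAAAGTTTGGATGAATCGCTAAATCGTCATACA
TAGCTTACGCACGGCATAAAGGCCGAGTCAGTGCCACTGCGTGCTGGCGAACGGCAGCGATGCCACACTG
CCCAGCCAAGCACTCCGAATATGAGACCGCTGTTAGGCTTATCCACGCCTACACGCGTATCCTCGTAGAG
CGGCTCAGTCGTATGCATCTTAATTCACGGCCAAAGAGCTGGGCTTGCTCCTGATACTTATATCCGGTTT
ACCTATATCTTAGGGAGCACTGTAGAATCAGTACCTCCCACCCGCCTAACAGACCCAATGACTCTTATTC
TGTATCTATCTAGGCCGTACTCGATAAACAACTCTAACATGAGAAGGATGGAGATCCGCTCGGATAACGG
CCTTGCTGCAAGTTGAGACGGAGGTCGTTACCGATAAATCCTTGACGCAGGGACTAGGACAAGCTGGAAG
GACCCGGAATCCGGCCAACAGAACGTGGGGCAATGACTTTAGGTATCTCGTACTAATCGAGCAGTGTATA
TTTTTCCGTCACGCCCCCCTGCCTGGAGAGTCTATTCGCTGTTGTGATAATACTACGGCATACGATGACG
CCTAGCCATGCGTGCTGCTT
>Polaribacter_synthetic_type_strain_16S
TAGCGTGTAAACGGCTTTGTCGTCCCTAGCGCCCAGTCGCTCTTCTGGATATACGGTTCGGTACGTCTGC
CAACAATCGCGATGCGATCGATCGGAGTAACTGGTTGACTTGAGTCATATGGGCGTAACCTGATCGCTTC
CTACATTACAAACTTTGACGAGATGGACACAGAATACCGATTGCGCTCCACGCTACGCGTAGGATCAGGT
GTGAGGAGTTCCAGTTTAACATTCCAGACTCAACATAAGCTATAAAACCTCCGCAACAATTACCTACGAG
AGACCCCGCCATGGGCACACAATTTTGGTCTTCTATCGGAGGGTTCAAGTATGATCCGCGATTGACGAGA
GGTGAGAGGTGGTGCCTCTCGCTATTTCCTTACTTATCCCATTTTGTGTATGTGCCCGAACCTATGCGAC
AAGCCACGTGGATTACCAAACGCATCCCATTGAAAATTCAAGACGGGGAGGATGTAAAAAAGAGGGAACG
TTAACTCTTAGGTTGACTAGCTTAGCACTACATTTTCGCCAACATTAAAAGGGCCCAATCGTAGCTACCC
CGTCAACGATAGGCCTGACGCCTGGATTATTACGGCTAGGGCGTTCCCGTCCGTAGTCGAGACTCCTTGT
ATAGGTAGGCCTGCTAGCAAAGCTGGCCTAATTGTGGTTAAGCGTCGCACCCGGACGGCTCCAGCGCCCA
GAACCACATAGATCCATCAAGTAAACTATTCGCTGTTGGGAGATTGACTCACACGGTAATGATTTTGGTG
GACATCTCCGATGTAGCCGCCCAGCGGGATCCAGTTGTCATAGTGTAGTACGGCTCGGCGAGTGAACCAA
CTGATGACGATGGAGGCGTCGAATATCCTTCCGCAACTCTGCTGACCAAGTCGTTTGGATACGAATAACA
TATTTGCCAATCTAGAGTTTCATTTTCTCACGGGGGACGGTCGTTCCACGTGGAAACTTGGGGTACCGTA
GGATCGAGTCAGAGCGCGGT
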