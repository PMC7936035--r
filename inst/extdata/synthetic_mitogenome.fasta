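>synthetic_vertgo
ATGCGTATCTCCCTATTCACAGTCAACAGCGAAGCGAATGTCCGAATCATATTACGAGGCAGCACCCAAGGCTATCATCG
CAGCTTACACCTAAAAAGCCTCCTCTTCGGGTCCGCCCAAGACGTGCGAGCTTCCACTTGTATACAAGGTAACCCCTGAG
ACACACACCCTCGCATATGCAACCTGAGTTTACTGATATGACGTTACAATAAAGCCGATGACCAGGATCGTTAAGGCGGG
TTATTGGGACTCCAGTCTTCTTCCATGGAAGCACCCTCATCACAGTCCCTTTCAATATTGGACATATCTAAGAATAACGC
CCGGTTCGGTTGTCTTACATCGGCATATTCCTACTGCTGTCCATAAAATCAAACTAACACCATGGCCTCTAACTTGATCG
CCTCTGCTCGACAAGATTCGCTAATCACAATGAATTCCGCCGAACCATCGCCTACATCTGTCTGCGCCTAAATGTGTAAT
TGCCTCAGCTTGCCGATTACCTGCCGCCACCGCGCAGTAGTATCTGCCTTAGACGCCGGGCACGATGACTGAGTACTAAG
CAACAGCGCTTAAATGTGACGGAGCCACATCACTATCGCCTTTTCATTCCACGTCCAGTATGAAGAGCAAACCGATATCG
CTGCAATACAATATATACAAACACTCCTCTCCACTATTTACTTCCAATAACTGAACACCATGCTGATGGTAGTCCACACT
GCTCTTCTGGTCCGCGTAGCTAGTCCAAACCAAACATCTAGCCCCCAAGCCACCAACACCGTCTGCAAAGCCTAATTATG
TCTAACCGAAATGATCGACCGTAGCTTAGCATGGATACGGCGCCCTACCCTGAACGTGCTCAGCTATGGACTACCCGACC
ATTTACGAATTCACTCATAAATGTACGTCGACAATTCAACTATAACACTCCAAGGACAAAACCTTCCTCCTCCAGTTGCA
TTTAACCAAATGCTTATACTTCAAGTACGCCTAAAACCATTGACCTACAAATCATACGTCCTACTCCGTCTAAACATCAA
CAAAACGTACCCCACGGTCGAACCCGACCCGCCCGACGTAATCTTATACCTGTTAAACGCGGCCTAATCTACCGCCGACG
CGTTCGATACATGCAACGGCCAAACCAAACATATGCCCAAGGAAAACGCATACTCTGCTGCCCGTTACCAGTGATTGGTG
AACCATAACCCAGTCGGTCCATCGTGCGGAGTATACCGATCGGTCCCCACCCTTCGAGCCTATCGATCCGGTCCCTACGC
CTGTCAATGACGCGTACGAGCGTCCCCATGACACTCCTTCCACCACACTGACTTTGGAGCGAACCGGCCCCCATGATATG
TCTACTCCTCTGCTGGTATCACGGCCCGGGGAATCGCCGCCATACGTATACTGGCTACACTCCGATAATTAGATTGGTGG
GCTTGCGGGCGTCCGGTATCGATCGTGGCGGACTGATAGTGTTAGAACAAATCGAGTTTGATGGTCTGCGGAAGCCATAG
AGTGGATGAGATCATGGAACTAAAATACCGAGACAGTGATAATCGCGTAGCGCTAGATTACACAACCAAATCCATAGACA
ATAAAACCTGTGGGGACGGTCTTTCAACAGTCGTCATCAATGGCTTAACATGCCTACCGTCATGGTGACATCCCTGAAGC
GACAAAGTCGGCATAAGCTTATAAAGAGCCAGTCTACCCGGTTAGTCTGGAGACCGCCGGGCACGACCACCCGCTACCCC
ACCTAACACTCCACCCCAGGCCACGATCAAGCTAACCAAACCATTCCTCGGCTCCATATTGTTGTGACCCCCAACCACAC
ACTCCACTCGCAAAAAACAGCTGCGCGGCACACTACTCTACACTATTTGCCCGCTCAATGGTTCCCCTTATTGACCTTGC
CTATCTCCCAACCGAAATACGTTTCTCCAAAACACTCAACGGGCCCAAAACTCACCCCTCTCCTCCCCTCAAGAACCTAA
CGGGCTTAAAAACTCAATAACTGCCCTCCCCTTAAGAGCTTTACGCAAACAAAGTGATTCGTACACGAAACTCTTCAGGG
ATAACTCTAACGCCTCAGACCCCGTACCCGCCTTCTAACACACTGCCTCTCCTGTAGCCCAGCTCATACATAGACCAGCC
CCGCACACAGACCTCCAGAACCCCCCGAACCAAACACCGCAGTCCGCTCTTTTGAATAATAGAAAACACCTGAGACTACA
ATAACTCAATATAGGAATCTGCCAAAATTAATCTCCTGAGCACTTCAACTCCAAATGCTAAGCCTCTCCAACTATGTGTA
GTCACTGGTCCTTAACCCTCATTCCACGGACCGACCACAACGTCAGTTCGACTCCCGACCTAAGTGTCGTCTGCCGAGAC
AGCTGAACCCATTCAATCCGAAGCGACTCAGTAACTTACCGCTTATGTCTAGCACCATAAACTTCACCAAGTACTCATTC
TGGGGTTAAGCCCCCCCATCAACGAATGCCTCGGATAGGCATGTCTGGAGTCCGCGCAATCCCTCATGTCCGCAAACACA
ATTACGAGGGATCCCTATGGCAAACATCCACGTGAACCGTACCAAAATACACAGCTAGCACAGGAATCTGACGACGCCAA
CTCGATGCACCCACCCGATAACTCTAAAACATCACGTCCAGGAAGCCATAGGGGATACGAGGTTTGCCACCAACAAATAA
TGAAGAATCTGTGGGAGGGATAGTGCGGTTA
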