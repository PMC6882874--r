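>scaffold_synthetic_7249 synthetic stand-in scaffold, 7249 nt (not M13mp18)
CATTCATAACCTCGTGCCAACTAGCGCGGTAGCCCTCTAACCATCACATTGTGTGCCTCCCCTTCGCAAA
GTCTTGAACCGGGACGACGTAAACCGCTTGCCCGTGGAACAATCCCCATGTGAACTACATATCTATGCGC
GCAGTTGAGGGTTCGAAAGTTGTTGAAGTGCGTAGACTCCTGCCCCGATCTCGTCAGGTGCCGATTGAGA
TTCCACGACAAATCCGCTTCATTCGGCTACCTCGCACGAATGTTTTCACCTTTTTTTTGAACCGGTTCAA
CCAATCATAGTAGTACGGCTAGTCCTGATTTGACCCGCATTTAATTCGCCACTGCACTAAGTGTAGGTAG
GATCGAGTCTGGAAATCTGATCAGCCCTAACGTGTTCAGCAGAGAGGCCAATTTTTAAGCCCCCACGCCC
GAGGGTGGTGATGAAAGTAACTTAACGTTAGTCGCTGCGCGCGGGGCATCTATATCGTACACTGCTCACA
TCCTGAGGGGTAACCAGAATCAACGCAATACATTAAATGTGACCTGTTGAATTGTCTATCAATCGGACGG
CCCAATTACACAACGAGCGCCCCTAAGTGATAGAAGTAATCGTCTTGTGGTCGGAGCAGCAGCGCCTACA
CAGGGAAGTTAATAGACCGTGTGCTGTAGTTTTCGAATGCCTTCGATATACGTAGTTGCCCTGTACCAGG
AAACACTAGATGTTCCAGCAGTATGTGCGTAGGAGTGAATGGGCTATACTTAGACCGCGGTAGTTGTAAG
TATACGCGAAAACTGGATACGAGCTGCTACCGCCTTCGGGAATTGCCCCAAGCACGCCGGACCGTTAAGA
TCTGTCCAGTCTGCGTAGATACCCCGTCCCCCTGTCACCTGGAACCTTGAGCGTCGTTCCTTCGAAATTC
CCGTCATTTAAAGCCGGTATAATCACAGAATAGTAAAGGAGGGCTCACGTGAATATCCTTAATCAATTGC
GCCGGAATCAGCCACATAGGAGCGGATCTTCCTTCCAAAACCTTGGGACACGTGGGGTGACCAACGCTAA
GAATATTCACGTGGGTACCCCCGTCCACAGATAATGGAAACATGTGAATCGACTTATACTGGGTCTCACT
CCCCCGGCGACACACCCTTTTATACTTTCGCTGGACCCTGAGTCGGCGTTGAGATTGCTCCTGACCAAGT
CCACATCGAGATCTCCTGAACATTTGCTCGGGGAGAGGTGCGCCTGTATTACCGGTATTGGAGACAGTTG
GGACGTATAAGATTAAAGAGAAAGTAAACCGACTGGAGTCGAGGGCACACAACTCGAGATATTGTTATTT
TTAATGGCGGGGCTTTCGCAATACTGTAAACAATCCGGACTTAGATGTTCCGTTAGGGAAGCAATTCTTT
TGTGATAAGTACGGATACAGTAGCGACGCTAGGCTAGAAGTAAAGGTAAGGCAGGCAATCTTCGTCTTGG
GGGCATATAGACCCGCGGCTTGTCACAATTGACATTCGCGCAAGTTGATCATTTCGGTAATCAACTCCTC
AATTTGAAACCAGCTGCAGTATGTGTTTTCCAGACACTACTGTCTTGGCGGGTAACATACTAGACTCCGG
TTTGTCACCGTACTACACACCTTGCTTGGAGTGCCAGGATCTCCGGGTGAGTCCAAAGGTTGAGATCGAT
AAAGTTCCAACGGGAGAAGAGGACGTAGGGTAGATGGCACAGAGCACCTCGTATTGTCCTGCCCTGTTAC
GAAGGTACAATGCCGGCAGGCCGTGACCTTCACATCCTTGGAAGCTAGTACTTACGAGAACACGCGGGTA
GTTACGATCACTCCCACCAGTACGGCTTCTAGGTACTATTCGGCCGGAAATAGCGTCTTTGGTAGTATAC
ATTCGCGTACAGCATGGGTCGTGCTGGAGAACAGCCACGCGATTGAACACGGCGGGTATCGCTCGATGTA
GCCAATAAGCGCCATGGGGGAGGCTCTCTTGTATGATGATCGGGCAGCACCCCAACCAATCCCGCCAATC
TCCTCTTCAGATAACGCCGTCCTACGTTGCAGCGAAATATAGGTTGAAGCGGATGAGATCTGAGTTGCGC
GATGAAAACGCCCGGGCAAAGCTGCCCAATTTAGTCGGCTTCCAAACCTGGGGACATATTACAGAGCGTC
CGGCCTTTCTTGGAGCTCGGTCCCTCGGTGAGAGCAGTGAAACGGAATGTCCAAGAGCCCAGCCAATGCC
GGTTGCGCGCCCGGTAAGAAGGCATACGCCGTGACGGCAGCCACAGCATGCCAAGGGGGCCCGGTCAATA
GGATATTATTGACCTCTAGTAGCAGTGTCCTAGATTACTTTTGTATTGTCGAGAAGCGGCATTTTTTATA
TGGTCGAAGGGGTAGATTGCGAAGGTCACTAACGTATTACCGAAAGTCAGGCACTTCGTAGAATGCTCAC
CATGGTGCGTCCGTTAGGTAGTTCGTCAAGGCCCGTCAGGTTGCCGCATTGCAGGAGTGCGCACGTCCGA
CTCAGGCTGGCACTAGATATGTCAAGGCCCGCCCTAGCCTTGATAATTGCGGTCCTTTAGTGTCTCGATC
GGATTTAATCCTACTCTGCTTGGGGTAGTTGAAGCCAGAGAAGTATTCGAATACGAAGGGGCCTACTCGG
CCTTACTCCTTAAAGGTCTATTAAGTTTTGCCAAGGAAGATTTAACATCCGAGATCCATCCGTAAAGCGG
AATAAGAGGCTAATCGCGTCGTGGGAACGGTTATCCCATGACGAACGGACTCATAGAACATTATTAGTCG
ACTTTTCGACATTGAGCGGTTCCGAGAAAGATCGCACGTAATGGAAATTGACTGATATGATCCAATAGGG
TGCGTGCATGATGTGTGCAGTGTTATATCTCATATCATTATGAAGTGTGCTTACGTTTGGGGCCATTCCT
TGATTCACAGATAAGTGAGTTAGTACGGCAACGAAAGGGGTGTTGGCACGCAGTACAAACCCGTCACAAA
CCCGGATGGACCCGGCTGGAGACTCATGAACTCGATCGGCTTTAGTCTCGTTTTTACCCGACTTTAAGTA
TGTTAGCTTGTAGCAAAGGACGTCTGCTATATAGAGTCTCCGGTATACCCGGTTAGAAGTCCGGGGAAAT
TAAATTTCGGCCTGCGCGCGATCAGTATTGAGGAGTGCCGTTGACCGGCTGGACCCAACGAAGATAGTGC
TGTTGCATCGGTCCTATTCTCAGTCGTAGTGAGCACAGCTTTGGCCGCTCTTAGACTCATAAGGGTGTTG
TGAATCTTAGAGCGCCTGGTACGTCCAAGTCGGGCGAAGTAGAGTTAGGTAGTTACGGCTGTTCTCTGTC
GTGTCTGTTCAGATGGGGATCCTGGCAAAGGGCTCTTATAGCGCTTATATCAGGGATGTCCCGTCCCGAG
CAGCCTGCTAGCACCTCCATCGATCGACACGATGCGCGGAAGATCGCCGTCAAAAAATCGACTCATTCCG
CAAGTGCCAGTAGCCTAAATCAACCGATTCGTTCATCGTGGAAGAAGGGCCCAATGTAGATGGACGAACA
CGGGAGCACTTTAACTTCATTCGTCGGATTAAGTGCCCTCGGGTGAAAGGCAGTTAACACAACGTGTAGG
GCTAAGTCACTTAAATTGTGCGGCTTGTTGGAATTACCCTGGAACATCTGTGTGCCCGGCATTTCTTAAT
CTGCTACATTTGTACAGGGACGTCAAATCAAGGCTGTGTATTACTTGATACTATTTAAGACACACATCAT
TGACGTACTTCGTTAGATTACACTGTGGGGTGCAAATATTTCTCCCTCTGTCCCAGAGATGAGGTGCTTT
GTCCACGGCTCAAGGTGAAGGGTGCCCCACAATATTACCTGACAGTCGTCATGCGGCTTGTTTACTCGAT
ACCTCGATCATTCCTAGTGTGCGTAGGAACGGATGTGTAAGTGTAGAGCTAACCTGCCTGCAGCTGTAAA
TTCATGCGCACGTCGGCATTCAGTCCTTTTCCGCGCAGTCGTCTGGCATTGCCTGATTGCGACACCAGAT
TCACGGCGGCGGACGTTGACCTTTCTTCATATACTCAGTGTCTCAAGCATTCTTGATTAGAACCCCCTGT
GAGGCTGCCATGAATATCTCTCAAGCTGCGGGCTGCGCGGCTTACCCAATGTGTCAGGCAATAATCGAGT
AGCCTCGGAGATATGCACACACCAGCAGGCAGATGCCATTTGAGGATCGTCCAGCAAGATTACACGCCCG
TTGGAAATACCGATGTGCTTTATGCCAACTACGGACGCCGCAATACACGGCGTGCAACGAGTTACAAGAT
GAGCAACATGAGGCTCTCGACCAACTGGGAGATACCAGGGCCAACGGACCGCGACTCACACGTCCGTAGG
GGCCCCTAGACCAAGCTACACCGGAAGCGCCTCACTACGCCGTCCGGTACGAGACTGTATGGACGTGGTG
GTGGACGCACCTCCGTCCTCACGACCTCTGAGTCTTGGTCCTGATTAGCTGAATTCCCTGCACCCATTTT
ACTTATAGTTCATTGCTCAGTGCGGTGACACGGTGAAGCTAATCAGCTACTTGATGTGCCCTAGGCCCTA
ACCTTACATATGGTTCTCAGATGGCTTGAAAGGTGCATGGCCTTAGTCGTTGATTAGACAAGACGGGCTA
GGGGCCGTTGGCGAGCAGACTGTGAACTCTAGTGTAAATAAACTGGTACAACTCGTCAGCGTGTTTGTCC
CGAGACCGGGATCGAGGGCATGTGCTGAGATCAAAATCTAGAAATGGCTTAAGGTAGTGTTAAGACCTGT
TTATATTTCTTGTAGCAGGTGACCAGATCAGGTCCTCCTAGACACGTGGTAAAACCAACGCCATCCCTCC
AGTAAGCGCCATAAGGCAGTACACGTATCTGTCTAAAATGACTAGGAAGTGCGTAGTTTTGAGTATTTCC
ACCCACATCGCTACTTCACAGTCAGTGGAGTACAGCTTAAACAACTTTCGTATCACAGAGAACAAGAGAT
TATGTCACCGTCTACATTCACGATTAATGCTTTGTTTGGTTTTTGGTGTCGAACCTTGTTGGCGGTGTTC
CGTACTTTGTAGGGGGAAAGAAAGGAGAACCATCCCCTACCGACGAACGTCGTTTTCAGGGAAGAAACTC
TGCGTCGCTCCCCTAATGCCCATTGTTTGGAGCGCCTCTTTATCTGCCGCTGCGGAAAACACGGAACAAC
CTTCGCTCAACCTAGTTCAACTATTACCCCGTTAAGAAAATACAGTTCTGCTCGCCTTTGCCCACCTCTC
CCGGCCGATTAGGGCTATCAGCCCAGATTGTGACCCAAGTAAGCTATTATGTGCGTGTAAGAGAAAAAAT
CCCACGACTAAGTTGCGCATTCCGTCGTGATCGGCCTCCTGTAATATACGTCCACAAGCTAATATCCAGG
GACTTTCGAGCACAGGTGCCATAGATGTGCCTGCAAAACGGATCATGTCAGAGTTAACCGTTTACATGGC
CTCTGCAGGAGCCACTCCGTGCGGAGCTGTATGAGTCGGCATGGCCCAGACAGATTACGGCACCACAGTC
TCTATTACGGACTTCAGGACCCGAGTAGAGATATTTCTGTTCGTGACGACCAGCTCACCTCGTAAGGGAA
TCATCCGAACGGTTATGTATGTTCCCAGATTGAATTAAGCACGGGAAGAAGACATGAGAGCTTCGCTTAC
TGGTACGAAGCGTTGAGCACGCGAAGCCGCACGGTACTTAAGATTGCTGCGCTCAGCTGCATTCGTGGCG
TATTGAGAAATTAGTCCAGTATCGTCTGAGCCAACCGCCCTCAATTATGGAAAACTTTCTTTAGTCCGAA
TCTTATGCGGATGCCTTGACCAGACCATACCTTCTATTGACTCGTGCTACATAGGCTGCACTTCAGGATT
AGGCTATGTAGAAATGACCTCTTGCGACCATTTGATTCACAAGTTCCCAGGCAGCAGTTAGCTTCTCTCT
TGGAGCCCGACCAGGGCTCCACAGCAACGAGTTCGGGATGCGACAGGACTGAGCATACGGTCGGGAATCA
ACTCAGACGAAGAGCCTGACAGTTCAACCATGCACTGCTGCGGCTTAAGGGAGTGGACTGCTTGGGTAAT
CTAGTGCGTAGCATGTAATAGTTACTTTTTTAGTACCTTAAATCAAAAACTGCGAGGTATTGCCAACCCC
TCCCCCCTACCCGATTGAGCGGGTTCGCTTTTTTCGCACGTTGTACGTAGGAAGAGTTGCCCATCAACCA
GGCGTTGGACATCCTCGGTCGTCAAGCGGATTGAAGGGGCATCAAATCCTACGAGTCTGAGTTTTAGGTT
TGGGTCTTCGTGTTATTGGCTGGCAGGTGAGCTCATATCGTTAATGGCGCTAGCAATTAGCTACTGGGCA
TCGACGCGTAGCTCTGATCACCTCCAGGAACGGAACTACCCCGGGATGCACGCATGTTAACGCCGTCGAG
TACGCACATTCGGTAGGAAGGTTCGTACCAAATAGATCTCTGGTTACTCGCCCCCCGTCAAATCAACCGT
TCCTGATTCTCGTGAGTCCAGTTCCTCTTCCACCCGTCATCTGAGCGATATTGATTTAGTGGATCTACAT
TGGCTGCCCCCCCTGCTTCGTCGTGTCGCGTGAATTGCCCGTGGGAACTGAGACTATCTTATAGAGCGAC
GGTGATCCGGTGGTGACTGGAAGGTAAACGCAGACCTCAAACTCGGGCAGGGCACACCCAGAACCATCCC
AGATATGTAAAAGAGTGCCGTGAGTGGTGCTGCAAAGCGCTCATGCCACACCAGTTACGAATCTCCGAAA
ATCGCATAAGCCAAGCGACTTATACGCGACGTCCCTCTAGCCGTGCGACATGGGCTGGTACTTCTAGTAG
CAATTGTCACAAGTAAGGGCTCCAGCACGGAAACCGGCCGGCAGAACGCGCTGTGCCGATTTAAAGTCCA
TGTGGAGCTGTCCTGCAGTGTAGCGATATTAAAGAGCTAGCTTCCCTCTTAACCGTTACACCAAGCGAAG
ATCAATAGATCCTAGTATCTCGAGTGGTCTCGCAGTTAAGAACAGACTAATGGCAGATGATTTGATAACG
ATGGCACGATTTGACCTCGGTCGGCAACTATAAGCGTTTTTTGCAATGTCGCCCACCCTGGACCTAGGAG
AAATGCGCTGGAATAAGACGTCCGCTCGCCGTGTGCCTA
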