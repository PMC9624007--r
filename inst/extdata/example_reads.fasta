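>genome01_read0001
GTCGGTAAGCGGCGAGCACGTGAGCAGGACGGCCAAGGCACGTACCCGTATGTTATCCGCCCAAGATAGA
TGATCCCGAAGCAACGTTGGAACATTCCAGAATGATGTATTGGCCGGTCCCATGTGGCATAGAAATCCAG
TACTTTCTATTGGGGGCTCCCAGCTTTGTCACTCGTTGCTCTGCTGCTCAGTGCAATTTTAGGAGGCAGG
GTGTGGACCCATTCTAGGCCGTAGTCATTCTTACCAGGCAACGGTAACCAGACGGAGCGTAGTATAGATT
CGCGCTCTCTCTCCGCAGTAATCTGCTTACTACTCTACACAATTTAACAGGTGACTAAACGCTTGGTTGC
AAGATATTGGGTATTGGGAAGTACGTGATATTCTGGAGTCCCCTGTAGATATGACAAGTCGCACAGTAAT
TGCACATCGCCAATCTGGAGTTCCGCACCTATTACATGACGCATCGCTTGCCGTGTGATATATTTAACCC
AGCCAATGGG
>genome01_read0002
CACCCTTTTGCCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGC
CAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGCTTAGCCTTAAAGTCCAACCGTAAA
GAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCACAGACG
GATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGGTCAACAGATATGTGT
GGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAG
GGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAA
CTACGAGACGTGAGGCGTATAGAACCTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAG
TGTGAAGTAT
>genome01_read0003
GGTATTGCACTTTTTAGTACCTGTCATTATCAGTAAGCTACACTAGTGGCATAACGGTCTTCATTGTTAA
CGCTGGGGAATTTCAGACGTAGTAACCTCAGCGCACGTCTTAGCTATGTCGGTAAGCGTCGAGCACGTGA
GCAGGACGGACAAGGCACGTACCCGTATGTTATCCGCCCAAGATAGATGATCCCGAAGCAACATTGGAAC
ATTCCAGAATGATGTATTGGCCGGTCCCATGTGGCATAGAAATCCAGTACTTTCTATTGGGGGCTCCCAG
CTTTGTCACTCGTTGCTCTGCTGCTCAGTGCAATTTTAGGAGGCAGGGTGTGGACCCATTCTAGGCCGTA
GTCATTCTTACCAGGCAACGGTAACCAGACGGAGCGTAGTATAGATTCGCGCTCTCTCTCCGCAGTAATC
TGCTTACTACTCTACACAATTTAACAGGTGATTAAACGCTTGGTTGCAAGATATTGGGTATTGGGAAGTA
CGTGATATTC
>genome02_read0001
AGTCTTACCAGCATCAGGATGACGGCCTGTGTGGACTCGTGTCACATCGACATTTCTGACAGCAGTACTG
GTTCGTATTCCCGTATATCACACGCGAGCGAAACGGGCTGCGGTGTATATTAGAGCACTTATGAAAAGAC
CGGAGTCTATATTGTTATGGACCGTGGAAATATGCTCCCTCCCGGTGGTGCGTCGGCAAAGCCAGTTTGC
GAGACATGCATCTGGTACTAGTGAACTGTGAGCTTAGTTCTCGAGTCCAAACGAAGGACTTCGAGCCAAT
CCTCTCACTGGCGTACTGATTTCTTTAAGATACGTTGCCACCTTTCGTTCTGGTCGCTGTCGTAGCTTGG
TCTAAACGGGAATTCTATATACTCCTAGACGTGTCATATTCGCTCTTTCATATTGAAGCTCATCCTGGTA
TTCCCTCCACCTTATGTTCATGTAATTCTAAACCGGAGACCGGGTATTGGGCTTAGTCTGCATCCGAACA
TATCTTGCTA
>genome02_read0002
ACATCGCAGCACAGGTGCACCGGCACGGTTGAGCGCTGCCAATGGGCAAAGAACGAAGTGCGAAAGACCC
GGCTTTGCACAAACAAACCTTGGTGGCAGGTGCTGTCTACTAGTGAACTCTCCGACCTCAACCACGTGGA
TCGACATCAGTCGCTGCTCGGGATATCACCAACCCCCTTTACGAGATTACTTATGAGCGGTACTCGCCCG
AATTTGGTTACTGTAGACAACGCGTTGTGATGCGGAGGGAGATACAAGTCCTATCTGGATTCTCGACCTC
GGGAGCCGCGGCTTCTAGATTACCGTGATTTTCGACCCTAACCTACGGCGTAACGCGTACGAGTGCACCA
GTAAATCCCGTTAGAGACGCTGTGGAGCCGTACTTCAGTGTAGGTGGGTGGACCCTACACTCCGTAGGGT
AGCTTCTTGCTTTCTGAAACCAGCAGGAACACAAGAGGCGTGGATGCAGCAGTATCACCTTAAGATTGCC
GAATGCGAGG
>genome02_read0003
AATTCAGTAGGCTCCGATCAGGCGTTCGGTTACATACGTGACCGACGGCATGTGCTTGACTATGCAGGCG
TAGCAAGAGATGTTCGGATGCAGACTAAGCCCAATATCCGGTCTCCGGTTTAGAATTACATGAACATAAG
GTGGAGGGAATACCAGGATGAGCTTCAATATCAAAGAGCGAATATGACACGTCTAGGAGTATATAGAATT
CCCGTTTAGACCAAGCTACGACAGCGACCAGAACGAAAGGTGGCAACGTATCTTAAAGAAATCAGTACAC
CAGTGAGAGGATTGGCTCGAAGTCCTTCGTTGGGACTCGAGAACTAAGCTCACAGTTCACTAGTACCAGA
CGCATGTCTCGCAAACTGGCTTCGCCGACGCACCACCGGCAGGGAGCATATTTCCACGGTCCATGACAAT
ATAGACTCCGGTCTTTTCATAAGTGCTCTAATATACACCGCAGCCCGTTACGCTCGCGTGTGATATACGG
GAATACGAAC
>genome03_read0001
TACCGTTGCTAACGCATGTTAGTCATTTTCAGATTCGTAGGGACTATTATCCCTTCGCAGAGTTCCTACG
TATATTACAGTTGGCTCATAGGACGATTTTCTTGTAAGCTATTCTCTCACTCGACGTCTGGCTGGGAATT
TTATACAGGTCTTCGCGTCTCAGATTTCGAAACATATACCGCCGATAGGTGAATCCACTCATCTAGGGAG
CCCCGTCCCTTGACTATGTGGCATAAAGGAATTGAAGGTATCGTTCTGGTATCTCAGTTGTTGTGTCGCT
CTGCCAGTACGTAGCTGATTGTTGTCGAGTCAATGATTAGAGCACCTGTACTGGGATCCGAGGTCGTCCC
GACTTAAACAGGCCCACGGGCATTGGTTTACAACCAAGTACCACGCGTTGGCTCTCTGAGTATCGTGGAA
AGATTAAGCGATGGGCGTCGTATTGTCGATCGGAGCGGCCCTAATTTGCTCCTCTCCACCTAACATGTGG
CGCTACATTC
>genome03_read0002
AGAAGGAATTAACTGGTCAATCGTTTTAAGTCTGGCTGTTCACTCCTGCTACGTGGGGGCCGTGCAGGGT
ATGTCACAAGCCCTTGGGGTACCCCATCGTAGATCACCGAGGGCATTCTTACTCAGATCTAGTCAGATTC
TTCGGAGCGGGCTTAAGCCTACTCACATCATTCCGCGAGAGGACGTAAATGTAAGGGGTTACCATAATAT
TCGCAAAATACTATCCGAAATTTGTGTTCGCCCAGCGAGCGGGCCATACGCGACTGGAGATACAGCTTTC
ATAAGTCTCGTGATAGACAGGGCGCAGTCACAAGAAATGGGATTGCACTATGAGACGATATATCCACTAG
CCCGGGCATGATTGCCCCATTTGTGGACCTCTGTGTGCCTGTTTGGTAACATGGGGAACTCACCAGCCCA
TTCGAGACTACTTCCAAACGAATGCCATTTCCTAGACTACTCGTATGCCAGGAAAGCACACCCATAGCCT
ATTGAACATC
>genome03_read0003
GTCCAGAAGTTTTAGGGCACGTTGATAATATGGGGGGCTTCTTTTATTTTCTTCGAATATCGTCTCTTTA
GTAAAAAGTAGTCTCCTGAACGTCTTGTATATTTTGGTCTCGGCGGCACGGTAACAACGAGCTCGGAGGG
TCACATTAACAGCATTAGATTACCGTCACTGTTTTGATCGACGACGTTTTTCGATCGTGAATCATAGAGC
ATCTGAGAAGAATCGCAGCGAATATGTCGGATCAAACCATCAGAGGAACAGCTGGCGCCCCATCTGCTAG
TTCCCGCTAAGCACAATTCTTGTAACCTCAAGATTAGAGGAAGCCATTAGGTCGGTTCTCACAGGGCACC
TACTAGGTCATGTGCCGCAACAGGGGGACAGGCTTGGGGAACAGATCCCCGTTTGCGGAACTTACTAAGG
CCAATAATAACTGAGGAGATATCCGCAGTGGCAGGCCGAACCGCACGGCTCCATGGTAATCCCATAGTGT
TATCGTGAGA
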