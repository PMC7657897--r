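>cps3_cds_synthetic synthetic stand-in CDS with primer sites at 399 bp geometry (not the real A. alcalica sequence)
GTACTCGACTAAATATTATCGGCTTCACTGGTTCCGCCACCTCGCTGCATGCGGACGTTG
TACGCTGGACCAAGGTAAATCCATCAGAACACGTGGTTCCGGAACTACACCCTCGATGGC
GATTAAGGAACGTTTACAGGACAACTAGCACAAAACGCTGGAGCGGACAAGGAACCTCAA
TTCAATCGTACGATTAGAGAATTAGGCCCGGAAGAACGGTTGACTTATTAAAAGCGGTGC
CCTGGCGTTGAAGACTTCCAGTCTTTTCAGATTGAGAGCTGAGGCGCATCAGAGTGCACG
CAGTGGGAGGTCAGATTGCACGGGTTATGGGGCGTGTGCTGAAGATCAGATAACAATGAG
ATCTTGCCCTCTGGGCCATACAGTCTCTGCCGGCTAATGTCGACTGCGGATAGATTTACG
TGGTCGAACGTTCCAAGCCTTTCCCGGCATAGACGAAGTAAGTGTTACTAGCTCTTTCTG
CAGGTGACATAGCCATGTTTGACCCTTATCATTGAAGTTCGCGGTTTAGGCCGACGACAT
CCATTGGAATGCGGCCAATCATGCGGGAGCGTTTTGCCCCGGCTCCTGGGGCACTGGAAT
GAATAATATGCCGCTGTTCGCTTGCCTTCCTGTAGGTAGGTTAGCCTGTTAGATAGCATG
ATGGTCGCTCGTGCGAGAGACCCTGTGCTTCGCTGTGAGGCCTCCTAAGTCCTGACATAG
CCAGGTGGATGTCCCGGCGCTCAAATGGTGGAATAGGGTTCCACCTTCGCGACCGTACTT
ACAACTCCCGTTAGTCCACAGCCGTACCTAATGGTCGTGCTCAGGCAAGCGTGTTTATCC
CAATCTACTCCCACCTCCTAAATCTGGTAAAGTTAGCTATAGCTAAGAAATTGCCGACCA
GATAAGGCCTTCAGAAAACGAAGGATCGTATTAAAGAGACCATGTACCCGGAATCGGCCA
GCATCCCTTTATAGCGACCAGTTTTTACCGTCACCCACTAGCCTTGCCCACACGATTCGG
TATGTCTAAGGTGGGTCCACGGCCGAATATAATTGTCGCGATGACTAACAACCTTTAGCG
GCGGTAGGCTGTCAAGCTTAAATCTGTCCGGACCTAAGAGAAGAGCCTTCACGGGTACCG
GTTAGGGTAATCGTGAGATCAGGTGAATCTTTAAGGCTCCACGCCCACCTGTAACTCGGA
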