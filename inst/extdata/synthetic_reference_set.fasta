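>Trebouxia_jamesii_SAG2103 genus=Trebouxia; species=Trebouxia jamesii; clade=S
AAACAGGTTTAGTCCTGGACATCCCCCAATTATGTGGCATTCCATAAATAAACATGGTCCAAGATTGATAGGAAGAGTACTAGGTATTCATAGTGCTTCATGGAATCAAGTGATAATAAACTGCAGAAGCACTCATCTACTAGGAAAATAATGACTTTAGCCACGCACAGTCCACCGTTTTACATGACTCGGTAATTTTTTGGCTCCCAATTGAGGACGGGACCGGGTCTTCTCGCTATCAACTCCACCC
>Trebouxia_asymmetrica_SAG48.88 genus=Trebouxia; species=Trebouxia asymmetrica; clade=G
TCCCGATAGGCATACGAGAATTCCGGCTCTTTCTATACGAACCTCGGTAGTCATCGACGAACCTGTGAGCAACCGGTTAAGGCTACCTTACCGATTTTCCTTGTTCTCAAGCAATCTCCCGAACAGCCTGCGTAGATTCTCCAGGCCAAGGGGCTCGGTTGACTCAGTGAAACCTTCGACTGTAACTCTGAAACAACTCGCCTCGAACGACAGTCGAGCAGCTCTGCGGATACCAGAAGTCCCCATTTTG
>Trebouxia_sp_TR9 genus=Trebouxia; species=Trebouxia sp. TR9; clade=A
GTACGCTCGTCTTTGTGTCACGTCCCAGTCTACATCAGTACAGTCACATGGTCCTGGACGGTACAGCGCTCAAATCATGAACCCCGCATCGAAAAATTCTCGTGGCACCACGTTCCGTAACTAGTTCAGAGTAACGCGTGGTCTCGTGGCGACAAACAACACCTTAGACCTTGTCCGAATCTTGCTATGCTCATTCGGACATTAATCCCTGAACGCAATTCTATCGATGGTCACGTCAGGGCACAAACGC
>Trebouxia_impressa_UTEX892 genus=Trebouxia; species=Trebouxia impressa; clade=I
TGCTGGTTACACTATCGTAATTTCTAACCGGCTTCGGAGTTTAATTTACAAGTGGCCCGATCATCTAACCATCGCAAGGGCCCGGTCAACTTGTAGGATCAAATTCGCCCGACAGTGTTACGCGTGGTATCGATGTACACCGTTAGTATTCAATAGTGGCCAACCGTACAGCGTCGCTCTCGATGTCCGCCTAGTTATCGTTGCGGTGTGAATCAGCAGGCCCTGCGATTAATTATAATACACCACTTCG
>Asterochloris_mediterranea genus=Asterochloris; species=Asterochloris mediterranea; clade=C
GGTGGGGCTCTCCAAGTACTACAAGAGGTTTGCTTCAGGACCAGCTTGGGTAGAGGCACCTTTCCGTTAATAGAGGAAGCTACGGGCCATAGTCAATCAGCTTGGCGTAAGTTCATGCCCGGTCTTGCACGGGCACGCTTCTGACCGGATAAAGATATAAAATGGACAAAATACTGCACTAATCCCTCCTTCTTATTTGCGGTCGCGCCCGTCGGTCAGTAGTTAGATCATGGTGGCGAAATGTGGATTC
>Asterochloris_sp genus=Asterochloris; species=Asterochloris sp.; clade=A
GGAACATCGTCTGTCCGGCACGCGCGAACTGTGGTGCACGATGGTTCCAGAAGAAGTACCAAAAAGCAGCATAGGCTGCATTTTTCCGACGGAAACTACCACTTAACGGAACCGAAAGTGAGAATTACACGGTCTAACGATTCATCGCGAGTGGGAATAAGCCTACTTTCTCAGTACGACGCCTCAAAATTAAATTTCTCAGCTTTTCCGGGTTCATACATCGACCGGTCTTGCTCTTCGCCTTAAGCGC
>Elliptochloris_sp genus=Elliptochloris; species=Elliptochloris sp.; clade=NA
GCCCGGACAGCGCGCGGGAGGCCTGCGCCCCTCTGCAACGGGGTTACAATCGCCGAATCTCTTTTCATTGACTGACCGCCGTGGACATTGACTTAAACTACGGTGGGCACGGCGCTATGCACCCTTGACAGTGCAGCCGAGTGAAGCCAATTGCACGCGTGGCCACAGGCTGTAAAAAGGCAGCCGCCTAATACAAGAGATCAGTGTGCCGCTTGAAATATGCGAGGGAATTACCACCCACGTGACGACA
>Vulcanochloris_guanchorum genus=Vulcanochloris; species=Vulcanochloris guanchorum; clade=NA
TGTAGCTAGGTAGGGCACCCAAAATATGGTAGCGGCTGTATTTAACGGGGGGTGGTTACATGCAGCATTTGTCCGTTTTAACTACCTCTTCAAAAGTCAAGTTGCTCCCAAGGGAAGGCGCCAACGTAAATAGAAAACTGGTAGAGACGGTTACGAGATACTCGAGATCAACGTATGAGGGCCACTCCCGTTCCTACTCGCATGGAGTGAGAGCATGAGTGTTCGACTCAGTGCTCGTTTGAGACGACTT
>Diplosphaera_chodatii_UTEX1177 genus=Diplosphaera; species=Diplosphaera chodatii; clade=NA
ACACGGCGCGAAATAAGCTATGTGCAGGGAATCGCGGTTCGTACCGGCTCTGCTAAACTTCAGAATTATCGCAGCGATAATCCTGCTAGTGAGTCCCCGACACTTACCGTGCCTGAGCCCCGACAGGTTGCGTTACTAAACCAGAGGGTAGAAAGTGAGTTGTGCCTATACAAGAATTTCAGAGCGAGCGAAAGAGAGTAGTTTCGCGGACCTCTGCGGTTCTTGTGAAGCTGCAACGCAAACACTAAGT
>Chlorophyta_sp_URa26 genus=Chlorophyta; species=Chlorophyta sp. URa26; clade=NA
GGTATCCATTGCAGACATTGCCATTCTTTGGGGGTACGATCAGGTTTATGATTCAATTAGTCGTTTACATTCTTGGGAGCCTGAGGAATAACTCTAATCGTAGTGCCGCCGCATGCTCTATACTACGCATACAATACCCCGCTCGTTGATCTACTTTATCTTGATCACTACCTCTATATATCACTCTGTTGGCAAAGTAGGGGGGCAGAGTACGAAAATGGAACTTAGTCTGTGCTAGCGTATCCGGTCT
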