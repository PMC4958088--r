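marker,linkage_group,motif,forward,reverse,tm,dye,core
TM447,LG01,(AAAAG)5,TGTTGTTAACGGTGTTCGGA,GCATTTGTTTTCTCTCTCTGCC,52,TAMRA,FALSE
TM514,LG02,(TCA)5,ATGTCTGGCCGTGGATTAAG,ATGGCAGGCTGTTCTGATTT,52,FAM,FALSE
TM480,LG02,(GTA)5,CGAAGAGTCGTTTCGAGGAG,CATCCCTTGTCTTCTCCCCT,52,FAM,FALSE
TM337,LG03,(CCAATT)6,GTGCGGCAAAGCTGTCTTAC,CTCCATCTCCAAACCC,60,FAM,FALSE
TM453,LG03,(TTC)6,AAGTCACAACACCACCACCA,GAGGCAGCGATAGTACCAGG,52,TAMRA,FALSE
TM343,LG04,(TGTTGA)3,ATCTTGGTAAGCTGCTCTAT,CATTGCTTTTGTTCTG,56,FAM,FALSE
TM445,LG04,(GTA)5,CCCAAATCCCAAGCTGTAGA,ACGATCGAGCCTGCAATACT,52,TAMRA,FALSE
TM502,LG04,(AGAT)4,TGTCTTTTGTGGTTTCGTGC,GGGAGACGATGGATCAGAAA,50,FAM,FALSE
TM422,LG04,(TTC)7,GGACTTCGTTGCTTCCTTTG,CCATTCTCGACGAATCCAGT,52,TAMRA,FALSE
TM369,LG04,(GAA)8,CGGAGCTGGAATCTGAAGAG,GGAAGGGTTGCAAATTCTGA,52,FAM,FALSE
TM523,LG04,(AAAAGA)3,TTTGCATTTTTGCCAAGTGA,CTTGCGTGACAATGCTCATAA,52,FAM,FALSE
TM589,LG05,(CTCCT)3,CACCACTGCCCAACAAACT,GAGGATGATGATTCGGGAGA,52,TAMRA,FALSE
TM428,LG05,(CAC)7,TCTCCTCCTCGATCCTCAGA,CCCTCTTCTTCGGATCCTTC,52,FAM,FALSE
TM341,LG06,(TCGAA)5,CGTACTTCAACGCTATAGCTCTC,TCTTCGGCATGGCTTCTAAAC,52,FAM,FALSE
TM415,LG07,(CCTTC)3,TCCACCCAAAACCTACTCTCTC,TATTTCGGAAACGAGCCATC,52,TAMRA,FALSE
TM426,LG07,(AGA)11,TGAGAGTGCTTGTCTGGGTG,CAACTACCCCTTTTCCCCAT,52,FAM,FALSE
TM324,LG07,(TTTTTG)5,CATCGTTTCATTGCTTATT,ATTTTCGGCATTGTCTT,54,FAM,TRUE
TM352,LG08,(GAGGTG)4,CTTCTTCCTGTCGGGTTGAG,GTCAACGGCCTATAACGGAA,52,TAMRA,FALSE
TM395,LG08,(TCTTTT)4,GATTGTAGGACAGCCGTGGT,AAGTTGGGGCTTGTTAAAGGA,52,FAM,FALSE
TM493,LG08,(AGG)6,GATAGGGACAGAGATCGGCA,TTTCCAACCTTGCTCAAACC,52,FAM,FALSE
TM442,LG09,(ATACAC)3,CAAGCCAAACCTTGCTGAAT,CTGTCCTGTGTCTGGTGGTG,52,FAM,TRUE
TM440,LG09,(TTTGC)3,TTGACCCGAATAAAATGGGA,CCTCAAAACATGCTTTTCTTAATC,52,FAM,FALSE
TM407,LG10,(CAAGAT)3,AACAACAGCAGCGAAGATGA,CCACCACTGATGACCCTTTT,52,TAMRA,FALSE
TM569,LG10,(GTGA)5,GCAAATTCGTAAGGCGAGAG,CTGACGTTTACCCTCGTTCC,52,FAM,TRUE
TM461,LG11,(ATTTTT)6,GGCTAGGGTTTCTCCCACTT,GAAGGTCGAAGCGATGTTGT,52,TAMRA,TRUE
TM581,LG11,(AAAAAC)3,AAGGATCACTGGTAAAAAGCCA,CTTCTGAGCCGTTCTTGAGC,52,FAM,TRUE
TM241,LG12,(GAGAA)3,ATCGGCGACGGTGGAAGT,GCCAGCGGAGAGGAGAAG,58,FAM,FALSE
TM499,LG12,(AGA)5,AACTGTGACACCGATTGCAG,AAGTTTCACTTGCCAGCACC,54,FAM,FALSE
TM425,LG13,(TTATT)3,CACGTTCGCATATTTTGGTG,TTGCTGACGACAACATTTTATT,52,FAM,FALSE
TM576,LG13,(TTTTC)3,CGCTCTTCCTTGTTTTCTGG,CACAAGCCATTGTAGAGAGAGAAA,52,FAM,FALSE
TM348,LG14,(TATC)7,GAGATGGCTTGCTCAAGGTC,CCCCAACCAAATCAAATCAC,52,FAM,FALSE
TM351,LG14,(GGAGAA)3,GGGTGAGAGTAAAGGGGGAG,AAACACAAAATCAAATTTGTCAGAA,52,FAM,TRUE
TM601,LG15,(GGA)5,TTGCACTGGAGTGCGATAAG,CATCGCCACCAAACTCTTCT,52,FAM,FALSE
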