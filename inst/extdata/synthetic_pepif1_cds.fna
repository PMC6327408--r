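>orf1_pepif1a
ATGTGGTTTGAACGGGAGTTTCGGGACGTTTACCATTCCGGGCATGATGCCCTGCAATACAGGCCACCAG
ACCATCACGACTGGGTTACTGCGATTCAGTGTAGACGCCAAAACCAGATTAATACACATCCGACCCCCAA
TATGCAGGGCGGGGACTATGCAATGTGGAAGATGTCGCCCGACGACAGTATATGTGAGTACCCGTCGGAC
GAAACTCACCACGAGTGGAACGAGATGTTTGCGCATAGGTCATGTATGAAAAATGCTGCACGTGAAGTAA
GATTTTGGGAGAAACAGTATGCTATCTATAATAAAATGAATCGCAGTGACAATAAGCCAGACTTAGCGCC
AGGTATTTACTCGGGCATGTGGCGCTGTTTTTGCTGGCACGAAACTGCCATTCTCCAGATCTGGGAATTC
TGGAAGTGTCCTTTGCATGAGCCCCAACACCTGGTTCGCAAAATGCAACAGGAGGAAAATAAGAAAAACC
TCGACTTAGCGTTCGAGGGCCCCTTCCGGACTAGTAACTTTGGCCCTCAATTCGCGATAACCTATACCGT
CAAACTGCATGAGCTGGGAAAGGCTTTCCCGGAAATCTTCCAAGAGCACCTCACGACAAACCCACACCCA
GATATTTTTTCCGAAGATCAATTCCATAACAAGGTTCATGTTCCCGAAAAATTTATTTATTGCAAGGTCT
CGGGACACATGATGTACGGAAATAAGTGCACGAGGTGGTACACGCATAACCATCACAACTGTAAAGCGCA
CAGCATGTGGCAAAACTGTGATGCGGATTGCCGCGAGGTCCGAAATTAA
>tpase_pepif1a
ATGGGTCACTCGGGAATAAATTTTATTTTTGATTGGCTCCATAAGTGGAAGTGGGAGATGAGGCACCGAA
TGAGAGCGGAGAGGCATAAGCACTGGCATATTAACGATCCAGTCAAGGCGCATTGCTATGAAGCACAAAT
GGCTGGGTGTCCTTACGAGAACTGCGTTTGTGCATTCTCACTACACAAGTTACTGAAGACGTGGCCCCCG
CAATACTGCGAAGACATTACGTGGACGTGGCCAGTAAAGCTTTTAATCGTTCAGACGGTATTTCAGCAAG
GCAGTACCATCCTTGCCGAGAACCGTCGGTGGGCTGATGACAAGGGGGTGCTAATGGTGCAAGGCGAATG
GATACGCTACTGCATCCAGCCTGCATGCGTTAAGATGGAGGAAGATCCGCTATTTGCGCCAATGCAGTCG
TACTGGGACTCCAACCATCAGAACCAGTATGGCATCCCCCAGAATCGCCCATGCGCTCATGAATTGTGGC
ATTGGTACTGCCATAAGGCTCGCTGGCAATCTTTTGCATCCCAGTATATGTTATTGTGCTTCATGACTGC
ACACATAGCCAAGACGGGGCGCCTGAACTGCTTTCTCGACACCGACCGTTTCATGCGTGACGGTCCAAAT
CATACCACATGCGAAACTATGACTTCCCAGAACTATGAATGGATGTGGTTCCAGTTGTTCTGGACCCTTA
AGACAGTTTATGAGTACCAACTCCTATCTCCCGAGTATTCATTAGCCGCTTGTGTAGATGCTGATGTTAT
GAGAGGTTGGAACCGCCTAATTGGCCTGTCTAAGTTTACTTGCAATCTGCAGGAGTGTTTATGCGGTCCA
AGCAAGTGTGGAGAGCTGTGCTTGCCACAAAAAAAGTGGCCTGGTGACCCGTATACACGTCCTAAGTGGA
TCCCTGCCAACCATTACCATCCATATGCCAATCATGACTATATTCCTGTCCAGACCTTTGTGCAGTACCT
TGAGTTAGCAGCGTGCAACAATCATAACGAATGGGTCCACCGGTCATGGCTGTCGAATATGTGGCATTGG
TACATTTTGTGTTTTAAGGCGGGGTTTTGTCCCGCTATTATGAACTGCTATGAGCTAATGGATTACCAAA
ACAAAAATTACAACTGCGCATGGGTATGGAATCCCCAGCACGTTGATCGGATTTATATGAATCAGTCCCT
CCCGAAACTAAAGGCGAACAACTCGATTCTGCTATGTTACTCTATAATCGATGCAGTTCACTGTGACCGC
GGGTCAATGGCCATATCATTTTAA
>orf1_pepif1b
ATGTTTGGAGAACGAAAATTCGAATGGGTCTATTCGAGCGGTGGAGATCTCAGATGGTACGGCGACCAAC
TCAGTGTCTGGTGGGTTGAATATGTTCCCTGGCTTATGCAGTGGATTATAAACGCGATGATTCGCATTCC
AACGATGGCAGATGACGCCTGGTTTACGAAATATAGCCCGGACGATAAAGAAAACGCAGACTGCTCAAAA
GAAATCCACCACGAGTGGTGGCTTATGTTTGCGCATATGATGGGGATGCAAAATGCCGCCAGGCGCGTAT
GCATGAAAGCGAAGTGGGGCGCTATATTTCAACTGCACTACGAGTCAGCGGCATACTGTGACCTTGCACC
GTGGTGGTATAGTAACATATGGGATAGCTTCTGCTGGCTAGTAGAGCCACCCTATAACATTTGGGAGACC
TGGGTTGCCCCATTTCACCTACCATCCTACTCAGTACGCGAGATGATGTACGAGATCGCAACAAACTGCC
TAGACTCCTTCGTTCAAATGCCCAAAGACGAACACAATAAGGGTCCATGGTTCACGATCTGCTATAACGT
AGATAGACATTGGCTCTGCAAGGGCTTTCAAAAGTATTATATCCAACATCTAAAACAGCGGATGCACTGC
GACGTAAAGATGGAAGACAACCTTCTTCATCACATGCATGTGTGTCACACGTTCTCATACTGTAAGGAAA
GCGGACACATGAATAAGCAGAACGCCTGTCCTGCGATTCAGACGCATGCTCACATAGAGCCACCCGCAAT
CATAATGTGGAACGTAATGTTCGCCTCTTGGAGATATATGTGGGTATAA
>tpase_pepif1b
ATGGGGTATTGCGGTAAATTTTTCATCCATGATTGGCTACATAAGCCGAAGTGGACCATGAAGCCGAATA
TGCGGAAGATACGACACAAACACACATATTCTAATGACCCTGTGTGGACACACTGTTCCGAGGCGTATGG
CGCGGGGTGCCTATACATACGATGCGTGGATGCGGCTGACCTCGCCATGTTAACGAAGACATGGTGCCCA
GAATCATGTGAACGCATCACCGGGCAAATGCCAAAGTGTCTCCTAATTGTCCAACAGGTCTTCCAGCAGG
GTGTGGCAATACTTAAGATATCTCGTCTTAGTGCCTATGCGAAAGGTAATTTATGGGCGCAGGGTGAATG
GCGGCCGTACTGCATTCAACAAAGAGACTACAAAGGGCAGGAAGATCCTTATGACGCACCGATGGACTCG
TACAGACTCAGCAATGACCAAAATCAAGTCATGATTTATCAGGGTCGGTTATGTGCCCATGAGCAGTTCC
ATTTTGTCTGCTGGAAAGTCCCTCATTGCAGTTTTTTCTCTCAGTACGTACTACTCCGCCGGATGATGGC
CCATAACGAAAAAACCGGGACACTGGCTATATTTCTCGACACTTCGCGATTTAGCCGAGACTTGCCGTGT
CACTACACATGCAACTGGTGCGCGAGAGTTAAAATGTTTTGGTCTTATTATCAGTTATGTGACACTCTCA
AGGACGTGTACTTCATGCAGGAACTTAAACATCCGGACCCCCATAATTGGTATGTAACGGCGGACGTCAT
GCATGAGGCCAACGGGCACACCTTACGTAGCCGGTGGACTTGTAATTTGGAGTCGTGTTTATGCCCGCAT
TTCAATTGTGGTTGGGCCAAACTTCCTCAATGTTGCTGCCCCGGAAAACCATTTTACATAGTCAAATGGG
GACCTTTCGGCCACAATCATTGGTACTCTTGCTCGGACTACTGCCCTACACAAACCTTTTGGGGACGTTA
CGAGTTGACGGCGATGAACCATCATAACGAATGGCCCCACCGATCCTGGAGGTTGAACATGTGGCATTGG
TACGTGATGTGTGACAAGGCCTGGTTCTGTCCGAGGATTATGAACTGCATTGAGGCCATGCCATGGCAGA
ACAAGAACAGACAATGTGACGCTGTATGGCTCCAAAAATATGTTAAATGCAAGGACCAGAATCAGTCACT
ACCGAAAGCCAAATGGAACGATTCACCTAAGCTCACATCCTCGCACGCGTATAATACACATGAAGACCGC
GGCTACGTTGAAATTAGTTTTTAA
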