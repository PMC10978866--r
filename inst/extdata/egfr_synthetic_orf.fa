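>EGFR_synthetic synthetic stand-in, pinned published residues
ATGATGATCGGCGAGTGCACCGCCAAGAAGGCCAAGGTGACCAGCAAGGGCAACGTGAACCCCCACAGCGTGCTGATCGT
GATCGTGCCCTGCGACCACCAGGTGTTCAAGATCTTCATCTGGCCCGACGGCTGGGCCCTGGAGGCCTACCAGGGCGTGG
AGCTGAACTGGTGGAACAAGCTGTTCGACTTCAACACCGACTGGATGACCACCTGGGTGGGCAACAGAGGCGCCTGGAAG
GTGAGACCCAGATTCATCAGAAGATGCGAGGTGAGACTGAGCCCCTGCCCCGAGACCAGCCCCGAGAACTGCTGCAGCAT
CAGACTGCTGCAGGACATGAACCCCGAGAGAATGGTGTACCAGCACGAGAAGAGACCCATCAAGAAGTTCCAGATGTGGG
TGCCCGGCTTCAACAGCCACCTGCAGAAGCAGAGACCCCAGCCCGGCGGCGCCCTGTGCCAGATCAGCTACCACAGCGAC
GGCATGCTGCCCGGCGTGAACATCCAGGAGCCCGTGAGAGGCTGCATCGCCATCTTCAAGATCCTGGAGATGTTCATGAT
GGACGACAACATCGGCCAGAACGTGAGCCTGACCCTGTGGAGCAACATGGCCAACGACAAGTACCAGGACAGCAAGAGCA
AGGGCCAGCTGCCCGTGGGCCAGAGAAGATACAAGTTCATGCTGAGCGACGACATCTGCCACAGCGGCGCCTGGGACAGC
AGCTACGTGGAGGAGAGAGGCACCACCGAGCAGCTGATGACCAGAAACAGAATGTACCAGTGGAGCGGCGAGGGCGTGAA
GTTCGGCAGCTACTGGAGCGGCTGCAGAATGCACATGAGAGTGGACGACTACGAGTTCACCAAGGCCCTGTGCCTGGACA
ACAAGTACTGGCCCATGAACGACACCATCTGGTGCCTGATCCAGAGCGAGTGCAAGTACAAGAAGGACCAGTGCTGGTAC
ATGGTGTGGAACGCCAGCTGGGGCACCGAGAAGTGCTGCTGGGTGTGGATCCAGTACAGCTGGGTGGACCACAAGGCCGA
CATCTGGACCATCGAGGAGCAGTGGACCCCCAGAATCAACGAGGTGCTGGCCAAGCAGAGCGACAAGATCTACCAGGCCG
GCCTGATGAGAGACGCCGTGCACAAGACCCTGATGAACCTGAGCATGAGAAGAAGATTCGACTTCATGTGCGACGACTGG
ATCACCAGAGGCATGAGAGAGCACAGCCACGACGCCATGTGGTGCCACCCCGACAGCAACGGCATCGAGTGCATCGCCAT
GGCCTACATGGGCCCCGCCCCCCTGTGCGACCCCGCCGCCACCACCAAGTACAAGTTCAGCTACGAGTGGGCCGTGAAGG
GCGTGAGAACCCAGAACAGAAGAAAGTACGTGACCAGACACGCCCTGAGACCCGGCATGTTCTACTACTGGAGAAACGAC
CTGACCAGAGACCACAGCTACATCCAGGCCTGCTTCAGCTACACCTACAACGTGAAGGAGTTCGCCAACCCCGCCAGCAG
ACCCCTGCACACCAGCACCCCCAAGGAGGGCATGGTGAGACACAGCGCCCACACCATGAGCAGACTGTGCGCCGACATGG
CCGTGGTGTACAAGATGGACATGCCCATGCACACCGTGAAGAAGACCCCCGAGCACATCTTCACCAACGGCCCCCAGTGG
CCCTGGGCCGACAAGCAGTACTGCCCCCAGTGCGACGTGGCCCACATCTTCCCCCACATGCCCTGCGGCACCCACGCCGA
CAGACACGAGTACAACTGCGCCTGCTGCAACGGCCACGCCGGCTACGTGTTCAGCATCCAGCAGGAGCTGTGGTTCACCA
CCATGTTCAAGAGCAGCTGCATGTGGCCCTGCAGCAGCAGATGCATGTGGTACATCCCCCCCCACGAGCACGCCATGTGG
CCCATCAGACCCATCCAGATGTGGTGGAACGACCAGATCGGCGGCAACGCCGGCATCATCATGGAGGCCTGCCCCGCCAG
CATCGCCCACGAGGACCCCCTGAGACCCAGAGGCAGAGTGTACCAGTTCGCCACCAACTACGTGGGCAGACTGTTCAACT
TCCCCGTGCCCGCCATCTACAGCGGCAGCGGCGCCAACACCTACGAGATGTGCCAGAGAATGAACCCCCAGCTGGGCTGG
AAGTACATGAGAACCCCCATGTACATGCCCTACTGGGACTGCTTCGAGGCCGCCATGAAGAGCATCTTCGTGTTCTGGCT
GACCTGGAGCGTGATCACCCAGGACAAGACCAAGTACAAGAAGAGAGACCAGAGAGCCACCAGCGTGGAGCACATCCACG
TGGGCCAGAACCACGGCGCCGACAGAGGCATGCTGCCCGCCCCCATCACCAACGGCATGATGCTGATGTGCTTCTTCAAC
GGCTGGTGGTACGAGACCCAGATGGAGGTGTACGTGGCCCCCCTGGACGAGAGAAGCACCGGCATCTGGCCCGGCATCAG
AGAGAGCCAGTGGGCCTACGAGATGTACAGAATCTGGGGCCTGTGCGAGTACCTGTGGATGATCTGGTTCGTGGAGTGCA
TCATCGACAGCCTGAACGTGCTGTTCAACCACGACGCCAGCCCCGTGAGAATGTTCAACGGCAAGGAGGCCAGAGGCGGC
ATCATGACCGTGTTCGAGCTGGGCAGATTCCCCACCCACGCCACCCCCGAGCACATCAAGCCCCAGACCCAGAAGGCCCA
CAGAAGAGACCACAGATACCTGAACCAGGACACCGGCCTGAGCTGGTACAGATTCATGATCCAGGGCGGCGACAACGCCC
ACGAGGCCTGCGGCCTGGCCCACTTCATGACCCAGGACCAGGTGCACGACGTGCCCTGCAGCGACTGCAACCACGACGGC
CAGCCCGCCGTGAAGGCCGCCAAGATGAACCTGCCCATCGTGTGCTGCGTGATCTACGTGGTGGACACCACCGGCTACTG
CTGCACCAAGGAGCACGGCTACGAGGGCGGCAGACCCGACGGCAACCCCAAGAGAGAGTGGCAGGGCTTCGTGGCCTTCT
GCGACTTCACCAGCAGCGTGTACAGACCCAGAGGCATCATCAACATCAGAGTGCACGTGAGAGTGCTGGTGAGAGGCTAC
AGCAGCCACAGCAGCTGGCTGTACAGCTACTACAACGACAGCATCGTGTGCATCCACTACTTCCCCAAGGCCGGCAACGC
CTTCCCCGACGCCGAGACCGCCCAGAGCAAGGGCGGCATCATCACCACCACCTTCATCGACATGTTCCCCAGATGCTTCA
TGAGCTGCACCATCGTGTTCATCTACGAGATCAGCGCCCCCCACTGGGCCTTCATCTGCGACGACATGGGCGGCGTGCAC
TGCAGAGACACCTGGAGCAAGGACCACGTGCTGTACCTGACCATCCACCTGAAGCACGCCAGCAAGCTGTACATGAAGAT
GAAGGTGCTGATCGAGATCCCCAGAAGCGCCGGCTGGAGCGCCAAGAGAATCCACGTGTGCGCCTACATCGGCTACGACT
GCGAGGTGGACGGCGGCGAGGAGGAGGGCGCCCAGAGAATCGCCTGGCAGCTGACCAACCCCAAGGAGATGTGCTACGCC
ACCTGGGCCGTGATGCTGTGGCAGATGCCCTGA
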