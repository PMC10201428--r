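>sfGFP_synthetic_cds 239-aa superfolder GFP; synthetic codon-normalized reverse translation
ATGGTGAGCAAAGGCGAAGAACTGTTTACCGGCGTGGTGCCGATTCTGGTGGAACTGGAT
GGCGATGTGAACGGCCATAAATTTAGCGTGCGTGGCGAAGGCGAAGGCGATGCGACCAAC
GGCAAACTGACCCTGAAATTTATTTGCACCACCGGCAAACTGCCGGTGCCGTGGCCGACC
CTGGTGACCACCCTGACCTATGGCGTGCAGTGCTTTGCGCGTTATCCGGAACATATGAAA
ATGAACGATTTTTTTAAAAGCGCGATGCCGGAAGGCTATGTGCAGGAACGTACCATTAGC
TTTAAAGATGATGGCACCTATAAAACCCGTGCGGAAGTGAAATTTGAAGGCGATACCCTG
GTGAACCGTATTGAACTGAAAGGCATTGATTTTAAAGAAGATGGCAACATTCTGGGCCAT
AAACTGGAATATAACTTTAACAGCCATAACGTGTATATTACCGCGGATAAACAGAAAAAC
GGCATTAAAGCGAACTTTAAAATTCGTCATAACGTGGAAGATGGCAGCGTGCAGCTGGCG
GATCATTATCAGCAGAACACCCCGATTGGCGATGGCCCGGTGCTGCTGCCGGATAACCAT
TATCTGAGCACCCAGAGCGTGCTGAGCAAAGATCCGAACGAAAAACGTGATCATATGGTG
CTGCTGGAATTTGTGACCGCGGCGGGCATTACCCATGGCATGGATGAACTGTATAAATAA
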