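>1ATP_E_40-300 PKACalpha catalytic domain, reference numbering start=40 (mouse PKA C-alpha, UniProt P05132; numbering of PDB 1ATP)
LDQFERIKTLGTGSFGRVMLVKHKETGNHYAMKILDKQKVVKLKQIEHTLNEKRILQAVN
FPFLVKLEFSFKDNSNLYMVMEYVPGGEMFSHLRRIGRFSEPHARFYAAQIVLTFEYLHS
LDLIYRDLKPENLLIDQQGYIQVTDFGFAKRVKGRTWTLCGTPEYLAPEIILSKGYNKAV
DWWALGVLIYEMAAGYPPFFADQPIQIYEKIVSGKVRFPSHFSSDLKDLLRNLLQVDLTK
RFGNLKNGVNDIKNHKWFATT
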