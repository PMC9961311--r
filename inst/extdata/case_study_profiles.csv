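id,CYP1A2,CYP2C9,CYP2C19,CYP2D6,CYP3A4,provenance
1-Hexadecyl-3-methylimidazolium,0,0,0,1,0,reference_table
1-Hexyl-3-methylimidazolium chloride,0,0,0,0,0,reference_table
1-Methyl-3-tetradecylimidazolium chloride,0,0,0,1,0,reference_table
"1,3-Didecyl-2-methylimidazolium",0,0,0,1,0,implied_by_similarity_1
1-Methyl-3-octadecylimidazolium hexafluorophosphate,0,0,0,1,0,implied_by_similarity_1
1-Ethyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Butyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Pentyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Heptyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Nonyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Decyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
1-Undecyl-3-methylimidazolium,0,0,0,0,0,synthetic_standin
2-Amino-6-ethoxybenzothiazole,1,0,1,0,0,reference_table
Methabenzthiazuron,1,0,1,0,0,reference_table
Riluzole,1,0,1,0,0,reference_table
Tioxidazole,1,0,1,0,0,reference_table
2-Amino-4-methoxybenzothiazole,1,0,0,0,0,reference_table
2-Aminobenzothiazole,0,0,0,0,0,synthetic_standin
2-Amino-6-methylbenzothiazole,0,0,0,0,0,synthetic_standin
2-Amino-6-methoxybenzothiazole,0,0,0,0,0,synthetic_standin
2-Amino-4-methylbenzothiazole,0,0,0,0,0,synthetic_standin
2-Amino-4-ethylbenzothiazole,0,0,0,0,0,synthetic_standin
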