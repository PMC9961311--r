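id,cas,name,smiles,activity,case,role,provenance
1-Hexadecyl-3-methylimidazolium,61546-01-8,1-Hexadecyl-3-methylimidazolium chloride,CCCCCCCCCCCCCCCCn1cc[n+](C)c1.[Cl-],active,imidazolium,target,case_study_compound
"1,3-Didecyl-2-methylimidazolium",70862-65-6,"1,3-Didecyl-2-methylimidazolium",CCCCCCCCCCn1cc[n+](CCCCCCCCCC)c1C,active,imidazolium,source,case_study_compound
1-Methyl-3-octadecylimidazolium hexafluorophosphate,219947-96-3,1-Methyl-3-octadecylimidazolium hexafluorophosphate,CCCCCCCCCCCCCCCCCCn1cc[n+](C)c1.F[P-](F)(F)(F)(F)F,active,imidazolium,source,case_study_compound
1-Methyl-3-tetradecylimidazolium chloride,171058-21-2,1-Methyl-3-tetradecylimidazolium chloride,CCCCCCCCCCCCCCn1cc[n+](C)c1.[Cl-],active,imidazolium,source,case_study_compound
1-Hexyl-3-methylimidazolium chloride,,1-Hexyl-3-methylimidazolium chloride,CCCCCCn1cc[n+](C)c1.[Cl-],inactive,imidazolium,source,case_study_compound
1-Ethyl-3-methylimidazolium,,1-Ethyl-3-methylimidazolium (synthetic stand-in),CCn1cc[n+](C)c1,inactive,imidazolium,source,synthetic_standin
1-Butyl-3-methylimidazolium,,1-Butyl-3-methylimidazolium (synthetic stand-in),CCCCn1cc[n+](C)c1,inactive,imidazolium,source,synthetic_standin
1-Pentyl-3-methylimidazolium,,1-Pentyl-3-methylimidazolium (synthetic stand-in),CCCCCn1cc[n+](C)c1,inactive,imidazolium,source,synthetic_standin
1-Heptyl-3-methylimidazolium,,1-Heptyl-3-methylimidazolium (synthetic stand-in),CCCCCCCn1cc[n+](C)c1,inactive,imidazolium,source,synthetic_standin
1-Nonyl-3-methylimidazolium,,1-Nonyl-3-methylimidazolium (synthetic stand-in),CCCCCCCCCn1cc[n+](C)c1,active,imidazolium,source,synthetic_standin
1-Decyl-3-methylimidazolium,,1-Decyl-3-methylimidazolium (synthetic stand-in),CCCCCCCCCCn1cc[n+](C)c1,active,imidazolium,source,synthetic_standin
1-Undecyl-3-methylimidazolium,,1-Undecyl-3-methylimidazolium (synthetic stand-in),CCCCCCCCCCCn1cc[n+](C)c1,active,imidazolium,source,synthetic_standin
2-Amino-6-ethoxybenzothiazole,94-45-1,2-Amino-6-ethoxybenzothiazole,CCOc1ccc2nc(N)sc2c1,active,benzothiazole,target,case_study_compound
Methabenzthiazuron,18691-97-9,Methabenzthiazuron,CN(c1nc2ccccc2s1)C(=O)NC,active,benzothiazole,source,case_study_compound
Riluzole,1744-22-5,Riluzole,Nc1nc2ccc(OC(F)(F)F)cc2s1,active,benzothiazole,source,case_study_compound
Tioxidazole,61570-90-9,Tioxidazole,CCCOc1ccc2nc(NC(=O)OC)sc2c1,active,benzothiazole,source,case_study_compound
2-Amino-4-methoxybenzothiazole,,2-Amino-4-methoxybenzothiazole,COc1cccc2sc(N)nc12,inactive,benzothiazole,source,case_study_compound
2-Aminobenzothiazole,,2-Aminobenzothiazole (synthetic stand-in),Nc1nc2ccccc2s1,active,benzothiazole,source,synthetic_standin
2-Amino-6-methylbenzothiazole,,2-Amino-6-methylbenzothiazole (synthetic stand-in),Cc1ccc2nc(N)sc2c1,active,benzothiazole,source,synthetic_standin
2-Amino-6-methoxybenzothiazole,,2-Amino-6-methoxybenzothiazole (synthetic stand-in),COc1ccc2nc(N)sc2c1,active,benzothiazole,source,synthetic_standin
2-Amino-4-methylbenzothiazole,,2-Amino-4-methylbenzothiazole (synthetic stand-in),Cc1cccc2sc(N)nc12,inactive,benzothiazole,source,synthetic_standin
2-Amino-4-ethylbenzothiazole,,2-Amino-4-ethylbenzothiazole (synthetic stand-in),CCc1cccc2sc(N)nc12,inactive,benzothiazole,source,synthetic_standin
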