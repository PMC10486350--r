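# Curated starter epitope motif list.
# R5 rows: the four peptide motifs recognised by the R5 monoclonal antibody
#   (Osman et al. 2001) used in regulatory gluten ELISAs.
# DQ_core rows: native (non-deamidated, Q-form) 9-mer cores of HLA-DQ2.5/DQ8
#   restricted coeliac epitopes, after the Sollid et al. (2012, updated 2020)
#   nomenclature. Deamidated (E-form) variants are NOT listed: scanning is
#   against unmodified sequences.
# immunogenic_Tcell rows: confirmed immunogenic epitope regions with positive
#   T-cell assays (Tye-Din et al. 2010; IEDB), matched under the intact-core
#   (>= 9 contiguous residues) criterion.
# This list is curated, not exhaustive; replace via readMotifList() as needed.
motif_id,sequence,epitope_class,source,min_core_match
r5_QQPFP,QQPFP,R5,Osman 2001,5
r5_QQQFP,QQQFP,R5,Osman 2001,5
r5_QLPFP,QLPFP,R5,Osman 2001,5
r5_LQPFP,LQPFP,R5,Osman 2001,5
dq25_glia_a1a,PFPQPQLPY,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_a1b,PYPQPQLPY,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_a2,PQPQLPYPQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_w1,PFPQPQQPF,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_w2,PQPQQPFPW,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_g1,PQQSFPQQQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_g2,IQPQQPAQL,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_g3,QQPQQPYPQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_g4c,QQPQQPFPQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_glia_g5,QQPFPQQPQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq25_hor_2,PQPQQPFPQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
dq8_glia_a1,QGSFQPSQQ,DQ_core,Sollid 2012/2020 nomenclature (native form),9
iedb_226653,PQQPFPQPQQPFP,immunogenic_Tcell,IEDB epitope 226653,9
tcell_chor_B02_region,QPQQPFPQPQQPFPL,immunogenic_Tcell,Tye-Din 2010 B02-matching C-hordein region (curated),9
tcell_chor_B29_region,SQQPQQPFPL,immunogenic_Tcell,Tye-Din 2010 B29-matching C-hordein region (curated),9
tcell_chor_R15_region,IIPQQPQQPFPL,immunogenic_Tcell,Tye-Din 2010 R15-matching C-hordein region (curated),9
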