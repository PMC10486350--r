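# Curated wheat-specific contamination marker peptides. DVSPGCRPITVSPGTR is
# the HMW-glutenin tryptic MRM marker; the remainder are wheat-specific
# peptides observed in barley-beer discovery proteomics. User panels may be
# supplied to wheatPanel() instead of this default.
peptide_sequence,source
DVSPGCRPITVSPGTR,wheat HMW glutenin tryptic MRM marker
RIEMPGPPY,CM17 protein Q41540 (chymotryptic)
ACRIEMPGPPY,CM17 protein Q41540 (chymotryptic)
VEEQACRIEMPGPPY,CM17 protein Q41540 (chymotryptic)
DAEGQLPSRT,peroxiredoxin Q6W8Q2 (tryptic)
PDEKDAEGQLPSR,peroxiredoxin Q6W8Q2 (tryptic)
VEVEDGNILQISGERK,small heat-shock protein A0A3B6JKI7 (tryptic)
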