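gene	dataset	species
KRT15	hu_esoph_A	human
ITGB1	hu_esoph_A	human
XPC	hu_esoph_A	human
COL17A1	hu_esoph_A	human
CAV1	hu_esoph_A	human
KRT15	hu_oral_B	human
ITGB1	hu_oral_B	human
TP63	hu_oral_B	human
CAV1	hu_oral_B	human
ASS1	hu_oral_B	human
Krt15	mo_esoph_C	mouse
Itgb1	mo_esoph_C	mouse
Lgr6	mo_esoph_C	mouse
Cav1	mo_esoph_C	mouse
Krt15	mo_skin_D	mouse
Lgr6	mo_skin_D	mouse
Sox2	mo_skin_D	mouse
Cav1	mo_skin_D	mouse
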