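# Salt lexicon for the summarizer's salt_type column.
NaCl
NaCI
KCl
KCI
LiCl
MgCl2
CaCl2
(NH4)2SO4
ammonium sulfate
sodium chloride
potassium chloride
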