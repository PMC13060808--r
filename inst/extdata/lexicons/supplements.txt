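# Additive lexicon for the summarizer's buffer_supplement column.
protease inhibitor cocktail
protease inhibitor
lysozyme
glycerol
DTT
TCEP
β-mercaptoethanol
2-mercaptoethanol
beta-mercaptoethanol
BME
CHAPS
Triton X-100
Tween-20
Tween 20
NP-40
DNase
benzonase
EDTA
PMSF
DDM
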