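# Purification vocabulary scored by the extraction rules; one term per
# line, matched case-insensitively as a substring.
column
resin
buffer
elut
imidazole
dialys
his-tag
his tag
size-exclusion
size exclusion
lysis
lysed
chromatograph
superdex
sepharose
histrap
sonicat
wash
equilibrat
purif
eluate
flow-through
gel filtration
centrifug
clarif
imac
affinity
supernatant
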