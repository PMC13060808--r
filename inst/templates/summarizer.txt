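Convert the purification protocol below into a table with exactly six
columns: purification step, buffer name, buffer composition, pH, salt
type, buffer supplement. One row per step, in protocol order. Every cell
value must be copied verbatim from the input text; use None for cells the
text does not specify. Reply as JSON rows with keys purification_step,
buffer_name, buffer_composition, ph, salt_type, buffer_supplement.

Protocol text:
{{protocol_text}}
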