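Compare the failed purification protocol with the successful protocols
below. List each parameter-level difference (pH, salt, component
concentrations, missing supplements), recommend a specific modification
for each, and label every recommendation with a confidence of high,
medium or low depending on how many successful protocols support it.
Consider the target annotations (signal peptide, transmembrane spans) for
solubility hazards. Then write a revised step-by-step protocol. Reply as
JSON with keys differences, revised_protocol, annotations_considered.

Failed protocol:
{{failed_table}}

Successful protocols:
{{success_tables}}

Target annotations:
{{annotations}}
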