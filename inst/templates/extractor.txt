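You are given the methods section of a research article. Return only the
raw text describing the protein purification protocol: cell lysis,
chromatography (affinity, ion exchange, size exclusion), buffer
compositions, washes, elution and polishing. Return the text verbatim —
do not paraphrase, summarize or add anything that is not in the input.
If the section contains no purification protocol, reply EMPTY.

Methods section:
{{methods_text}}
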