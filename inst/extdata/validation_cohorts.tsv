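cohort	n_cases	n_controls
global	267	249
mongolian	46	121
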