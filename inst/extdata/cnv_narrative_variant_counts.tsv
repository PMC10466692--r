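label	n_diagnostic_positive	n_detected
Total (narrative counts)	249	159
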