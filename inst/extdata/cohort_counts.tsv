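label	n_diagnostic_positive	n_detected
CMA positive rate	452	335
Aneuploidy among CMA-positive	335	86
CNV among CMA-positive	335	249
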