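label	n_diagnostic_positive	n_detected
T21	29	28
T18	7	7
T13	1	1
Common trisomy	37	36
SCA	45	43
RAT	5	4
Overall aneuploidy	86	83
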