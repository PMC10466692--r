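label	n_diagnostic_positive	n_detected
1p36 microdeletion	2	2
cri-du-chat (5p15)	2	2
Williams-Beuren (7q11.23)	3	1
9p deletion/duplication	4	4
Angelman/Prader-Willi (15q11-q13)	3	2
RCAD (17q12)	15	11
DiGeorge (22q11.2)	13	12
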