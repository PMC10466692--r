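label	n_screen_positive	n_confirmed
T21	31	28
T18	8	7
T13	4	1
SCA	45	40
RAT	8	4
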