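gene	direction
Cdh244	up
Chd1	up
Chn2	up
Hpgds	up
Inpp4b	up
Itga1	up
Itgae	up
Qpct	up
Rgs1	up
Rgs2	up
Skil	up
Fam65b	down
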