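gene	score_category
EP300	1
CCNK	2
ZC3H11A	3
CPSF7	3
U2AF2	2
SRSF11	2
HLA-A	3
HLA-B	3
NUP155	2
NSD2	1
PSMD11	2
CREBBP	1
TBL1X	1
NOTCH1	1
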