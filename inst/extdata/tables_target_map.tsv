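miRNA	gene	evidence
miR-4722-5p	PSMD11	strong
miR-766-5p	PSMD11	strong
miR-942-5p	CREBBP	strong
miR-6875-3p	TBL1X	strong
miR-4738-3p	SRSF11	strong
miR-129-5p	NOTCH1	strong
miR-6832-3p	SRSF11	strong
mir-623	NOTCH1	strong
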