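# synthetic example annotation; families follow the conventional
# catalytic-domain grouping of the human kinome
kinase	family
MET	TK
ALK	TK
KIT	TK
ABL1	TK
KDR	TK
EGFR	TK
SRC	TK
CDK2	CMGC
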