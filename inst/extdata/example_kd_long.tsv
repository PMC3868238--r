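# synthetic example Kd panel (micromolar); not measured data
drug	kinase	value
inhibA	MET	0.002
inhibA	ALK	1.5
inhibA	KIT	4.2
inhibA	ABL1	8.0
inhibA	KDR	2.7
inhibA	CDK2	9.5
inhibA	EGFR	6.1
inhibA	SRC	3.3
inhibB	MET	0.004
inhibB	ALK	0.009
inhibB	KIT	2.1
inhibB	ABL1	5.6
inhibB	KDR	0.8
inhibB	CDK2	7.2
inhibB	EGFR	4.4
inhibB	SRC	1.9
inhibC	MET	6.3
inhibC	ALK	4.8
inhibC	KIT	0.003
inhibC	ABL1	0.001
inhibC	KDR	2.2
inhibC	CDK2	8.8
inhibC	EGFR	5.0
inhibC	SRC	0.4
inhibD	MET	0.3
inhibD	ALK	0.5
inhibD	KIT	0.2
inhibD	ABL1	0.4
inhibD	KDR	0.6
inhibD	CDK2	0.7
inhibD	EGFR	0.25
inhibD	SRC	0.35
inhibE	MET	9.1
inhibE	ALK	7.7
inhibE	KIT	8.4
inhibE	ABL1	6.6
inhibE	KDR	5.9
inhibE	CDK2	0.008
inhibE	EGFR	7.0
inhibE	SRC	8.9
inhibF	ALK	3.1
inhibF	KIT	2.6
inhibF	ABL1	4.9
inhibF	KDR	0.9
inhibF	CDK2	6.8
inhibF	EGFR	0.006
inhibF	SRC	1.2
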