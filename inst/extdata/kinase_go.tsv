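# synthetic example GO annotation (term -> listed kinases only)
kinase	go_id	go_name
MET	GO:0007169	transmembrane receptor protein tyrosine kinase signaling pathway
ALK	GO:0007169	transmembrane receptor protein tyrosine kinase signaling pathway
KDR	GO:0001525	angiogenesis
EGFR	GO:0007169	transmembrane receptor protein tyrosine kinase signaling pathway
CDK2	GO:0051726	regulation of cell cycle
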