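lesion_id	purity
FA1	0.5
FA2	0.6
FA3	0.5
BenignPT	0.4
MalignantPT	0.6
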