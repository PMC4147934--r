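subtype	ESC	PTEN_down	Proliferation	MYC_plus	PRC2	ERG_fusion	AR_signaling	Stroma	Basal	Luminal	Neuroendocrine	Hypoxia	EMT	Angiogenesis	Inflammation
BP-E/P/Pr	1	1	1	0.5	-1	0	0	-0.5	0.5	-0.5	0.5	0.5	0	0.5	0
BP-ERG	0	0	0.5	0	0	1	0.5	-0.5	-0.5	0.5	0	0	0.5	0	0.5
GP1	-0.5	-0.5	-0.5	-1	0.5	-0.5	0.5	1	0	0.5	-0.5	-0.5	0	-0.5	0.5
GP2	-1	-0.5	-1	-0.5	1	-1	-0.5	0.5	0.5	-0.5	0	-0.5	-0.5	0	-1
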