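sample_id	role	donor	medium	atmosphere
inoc1	inoculum	D1		na
printA	print	D1	MSPS_029	anaerobic
printB	print	D1	MSPS_029	anaerobic
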