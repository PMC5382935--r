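name	chrom	start	end	version
1p36	1	0	12500000	hg19-regions/1
22q11_DiGeorge	22	18650000	21800000	hg19-regions/1
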