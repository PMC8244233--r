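rsid	gene	class	coded_allele	weight
rs12785878	DHCR7/NADSYN1	synthesis	vitd_increasing	1
rs10741657	CYP2R1	synthesis	vitd_increasing	1
rs2282679	GC	transport	vitd_increasing	1
rs6013897	CYP24A1	catabolism	vitd_increasing	1
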