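gene_tip	species	copy_id
Priapulida_RUSML	Priapulida	RUSML
Nematomorpha_RUSML	Nematomorpha	RUSML
Tardigrada_RUSML	Tardigrada	RUSML
Chelicerata_Rh7	Chelicerata	Rh7
Pancrustacea_Rh7	Pancrustacea	Rh7
Chelicerata_UVSWS	Chelicerata	UVSWS
Pancrustacea_UV	Pancrustacea	UV
Pancrustacea_SWS	Pancrustacea	SWS
Chelicerata_MWS	Chelicerata	MWS
Pancrustacea_MWS	Pancrustacea	MWS
Chelicerata_LWS	Chelicerata	LWS
Pancrustacea_LWS	Pancrustacea	LWS
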