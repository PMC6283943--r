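((Priapulida_RUSML,Nematomorpha_RUSML),(Tardigrada_RUSML,(((Chelicerata_Rh7,Pancrustacea_Rh7),(Chelicerata_UVSWS,(Pancrustacea_UV,Pancrustacea_SWS))),((Chelicerata_MWS,Pancrustacea_MWS),(Chelicerata_LWS,Pancrustacea_LWS)))));
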