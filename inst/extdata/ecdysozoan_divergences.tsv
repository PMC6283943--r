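lineage	ci_young	ci_old
Pambdelurion	572	595
Opabinia	562	585
Anomalocaris	558	580
Fuxianhuia	539	562
crown_Arthropoda	519	540
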