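sample_id	phenotype	patient_id	lobe	sample_type	age	sex	fvc_pct	dlco_pct
Biopsy_140U	IPF	P01	upper	biopsy	58	Male	55	54
Biopsy_142U	IPF	P02	upper	biopsy	56	Female	55	65
Biopsy_144U	IPF	P03	upper	biopsy	70	Male	84	87
Biopsy_145U	IPF	P04	upper	biopsy	54	Male	68	52
Biopsy_149U	IPF	P05	upper	biopsy	58	Male	79	70
Biopsy_149L	IPF	P05	lower	biopsy	58	Male	79	70
Biopsy_159U	IPF	P06	upper	biopsy	68	Male	50	43
Biopsy_159L	IPF	P06	lower	biopsy	68	Male	50	43
Explant_146L	IPF	P07	lower	explant	64	Male	56	23
Explant_152U	IPF	P08	upper	explant	67	Male	53	29
Explant_152L	IPF	P08	lower	explant	67	Male	53	29
Explant_157U	IPF	P09	upper	explant	67	Male	51	34
Explant_157L	IPF	P09	lower	explant	67	Male	51	34
Explant_158U	IPF	P10	upper	explant	68	Female	78	18
Explant_158L	IPF	P10	lower	explant	68	Female	78	18
Explant_160U	IPF	P11	upper	explant	67	Female	46	42
Explant_160L	IPF	P11	lower	explant	67	Female	46	42
Normal_A	Normal	C01	unknown	control
Normal_B	Normal	C02	unknown	control
Normal_C	Normal	C03	unknown	control
Normal_D	Normal	C04	unknown	control
Normal_E	Normal	C05	unknown	control
Normal_F	Normal	C06	unknown	control
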