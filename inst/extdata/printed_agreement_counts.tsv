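metric	kind	k	n
strong_clinical_snv_ppa	ppa	35	36
hotspot_ppa	ppa	116	119
all_alteration_ppa	ppa	727	855
msi_ppa	ppa	79	80
msi_npa	npa	142	143
amplification_ppa	ppa	121	140
translocation_ppa	ppa	42	51
alk_translocation_ppa	ppa	13	14
lob_confirmation_fraction	fraction	60	63
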