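signature	etiology
aging	spontaneous deamination (aging)
msi_like	mismatch-repair deficiency (MSI)
brca_like	homologous-recombination deficiency
apobec	APOBEC activity
smoking_like	tobacco-associated
flat	unknown
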