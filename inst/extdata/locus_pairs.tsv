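name	chrom_gene	start_gene	end_gene	chrom_enh	start_enh	end_enh
AR	chrX	66764465	66950461	chrX	66113000	66145000
MYC	chr8	128747680	128753674	chr8	128025399	128033259
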