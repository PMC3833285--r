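# Restriction enzyme panel: name <TAB> recognition (IUPAC) <TAB> cut_offset
# cut_offset = position of the top-strand cut from the 5' end of the site
# (REBASE convention: MspI/HpaII C^CGG, RsaI GT^AC, FatI ^CATG, Kzo9I ^GATC,
# AluI/AluBI AG^CT, AspS9I G^GNCC, Bme18I G^GWCC)
MspI	CCGG	1
HpaII	CCGG	1
RsaI	GTAC	2
FatI	CATG	0
Kzo9I	GATC	0
AluI	AGCT	2
AluBI	AGCT	2
AspS9I	GGNCC	1
Bme18I	GGWCC	1
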