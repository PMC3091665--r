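name	recognition	cut_offset
AccII	CGCG	2
HaeIII	GGCC	2
RsaI	GTAC	2
DpnI	GATC	2
AluI	AGCT	2
CviRI	TGCA	2
CviJI	RGCY	2
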