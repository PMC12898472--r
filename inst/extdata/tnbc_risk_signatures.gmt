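SPSM	stress-response tumor cell / pDC prognostic model gene panel	STEAP4	TTC6	FMO1	ARHGEF38	BRINP3	ABCA12	TCIM	GRB7	TRIM17	EAF2
SPSM_IPSM_SHARED	genes shared between the SPSM and IPSM panels	FMO1	BRINP3	TCIM	TRIM17	EAF2
IPSM_PARTIAL	published members of the IPSM gene panel (partial list)	ANKRD37	PNLIPRP3	FMO1	BRINP3	TCIM	TRIM17	EAF2
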