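# name: synthesis_vs_TR
gene	group	synonym_of
DPM1	Synthesis
DPM2	Synthesis
DPM3	Synthesis
MPDU1	Synthesis
PIGA	Synthesis
PIGB	Synthesis
PIGC	Synthesis
PIGF	Synthesis
PIGG	Synthesis
PIGH	Synthesis
PIGL	Synthesis
PIGM	Synthesis
PIGN	Synthesis
PIGO	Synthesis
PIGP	Synthesis
PIGQ	Synthesis
PIGV	Synthesis
PIGW	Synthesis
PIGX	Synthesis
PIGY	Synthesis
GPAA1	Transamidase+Remodeling
PGAP1	Transamidase+Remodeling
PGAP2	Transamidase+Remodeling
PGAP3	Transamidase+Remodeling
PGAP5	Transamidase+Remodeling
PIGK	Transamidase+Remodeling
PIGS	Transamidase+Remodeling
PIGT	Transamidase+Remodeling
PIGU	Transamidase+Remodeling
MPPE1		PGAP5
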