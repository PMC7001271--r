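# name: synTA_vs_remodeling
gene	group	synonym_of
DPM1	Synthesis+Transamidase
DPM2	Synthesis+Transamidase
DPM3	Synthesis+Transamidase
MPDU1	Synthesis+Transamidase
PIGA	Synthesis+Transamidase
PIGB	Synthesis+Transamidase
PIGC	Synthesis+Transamidase
PIGF	Synthesis+Transamidase
PIGG	Synthesis+Transamidase
PIGH	Synthesis+Transamidase
PIGL	Synthesis+Transamidase
PIGM	Synthesis+Transamidase
PIGN	Synthesis+Transamidase
PIGO	Synthesis+Transamidase
PIGP	Synthesis+Transamidase
PIGQ	Synthesis+Transamidase
PIGV	Synthesis+Transamidase
PIGW	Synthesis+Transamidase
PIGX	Synthesis+Transamidase
PIGY	Synthesis+Transamidase
GPAA1	Synthesis+Transamidase
PIGK	Synthesis+Transamidase
PIGS	Synthesis+Transamidase
PIGT	Synthesis+Transamidase
PIGU	Synthesis+Transamidase
PGAP1	Remodeling
PGAP2	Remodeling
PGAP3	Remodeling
PGAP5	Remodeling
MPPE1		PGAP5
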