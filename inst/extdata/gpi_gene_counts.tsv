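gene	stage	patients
DPM1	Synthesis	3
DPM2	Synthesis	3
DPM3	Synthesis	2
MPDU1	Synthesis	1
PIGA	Synthesis	21
PIGB	Synthesis	0
PIGC	Synthesis	3
PIGF	Synthesis	0
PIGG	Synthesis	5
PIGH	Synthesis	1
PIGL	Synthesis	8
PIGM	Synthesis	3
PIGN	Synthesis	11
PIGO	Synthesis	9
PIGP	Synthesis	2
PIGQ	Synthesis	1
PIGV	Synthesis	13
PIGW	Synthesis	3
PIGX	Synthesis	0
PIGY	Synthesis	4
GPAA1	Transamidase+Remodeling	10
PGAP5	Transamidase+Remodeling	0
PGAP1	Transamidase+Remodeling	7
PGAP2	Transamidase+Remodeling	10
PGAP3	Transamidase+Remodeling	22
PIGK	Transamidase+Remodeling	0
PIGS	Transamidase+Remodeling	0
PIGT	Transamidase+Remodeling	10
PIGU	Transamidase+Remodeling	0
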