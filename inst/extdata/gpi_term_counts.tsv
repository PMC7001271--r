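term_id	label	count_synthesis	count_tr	p_corrected	enriched_in
HP:0011297	Abnormality of digit	31	4	0.03185	Synthesis
HP:0011805	Abnormal muscle morphology	25	2	0.04678	Synthesis
HP:0011927	Short digit	22	1	0.04883	Synthesis
HP:0001367	Abnormal joint morphology	22	1	0.04883	Synthesis
HP:0100261	Abnormal tendon morphology	19	0	0.04346	Synthesis
HP:0002360	Sleep disturbance	0	13	0.00047	Transamidase+Remodeling
HP:0012759	Neurodevelopmental abnormality	68	58	0.01235	Transamidase+Remodeling
HP:0000708	Behavioral abnormality	14	25	0.03610	Transamidase+Remodeling
HP:0012758	Neurodevelopmental delay	57	54	0.00898	Transamidase+Remodeling
HP:0001249	Intellectual disability	15	39	0.00000	Transamidase+Remodeling
HP:0003330	Abnormal bone structure	3	15	0.00773	Transamidase+Remodeling
HP:0011849	Abnormal bone ossification	2	15	0.00193	Transamidase+Remodeling
HP:0004348	Abnormality of bone mineral density	2	15	0.00193	Transamidase+Remodeling
HP:0004349	Reduced bone mineral density	2	15	0.00193	Transamidase+Remodeling
HP:0000938	Osteopenia	2	13	0.01305	Transamidase+Remodeling
HP:0000400	Macrotia	2	15	0.00193	Transamidase+Remodeling
HP:0002265	Large fleshy ears	1	14	0.00106	Transamidase+Remodeling
HP:0000366	Abnormality of the nose	26	36	0.01119	Transamidase+Remodeling
HP:0100737	Abnormal hard palate morphology	6	17	0.03743	Transamidase+Remodeling
HP:0000202	Oral cleft	6	18	0.01556	Transamidase+Remodeling
HP:0000175	Cleft palate	6	17	0.03743	Transamidase+Remodeling
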