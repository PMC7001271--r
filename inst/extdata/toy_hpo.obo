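format-version: 1.2
data-version: toy/2026-09
remark: Synthetic miniature of the HPO phenotype subtree for testing and examples.
remark: Real HP ids are kept where published count fixtures pin them; HP:9xxxxxx ids are toy filler.

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001 ! All

[Term]
id: HP:0011297
name: Abnormality of digit
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0011927
name: Short digit
is_a: HP:0011297 ! Abnormality of digit

[Term]
id: HP:0004100
name: Abnormal 2nd finger morphology
is_a: HP:0011297 ! Abnormality of digit

[Term]
id: HP:0011805
name: Abnormal muscle morphology
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001367
name: Abnormal joint morphology
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0100261
name: Abnormal tendon morphology
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001371
name: Flexion contracture
is_a: HP:0001367 ! Abnormal joint morphology
is_a: HP:0011805 ! Abnormal muscle morphology
is_a: HP:0100261 ! Abnormal tendon morphology

[Term]
id: HP:0012785
name: Flexion contracture of finger
is_a: HP:0001371 ! Flexion contracture

[Term]
id: HP:0009537
name: Flexion contracture of the 2nd finger
is_a: HP:0012785 ! Flexion contracture of finger
is_a: HP:0004100 ! Abnormal 2nd finger morphology

[Term]
id: HP:0003330
name: Abnormal bone structure
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0011849
name: Abnormal bone ossification
is_a: HP:0003330 ! Abnormal bone structure

[Term]
id: HP:0004348
name: Abnormality of bone mineral density
is_a: HP:0011849 ! Abnormal bone ossification

[Term]
id: HP:0004349
name: Reduced bone mineral density
is_a: HP:0004348 ! Abnormality of bone mineral density

[Term]
id: HP:0000938
name: Osteopenia
is_a: HP:0004349 ! Reduced bone mineral density

[Term]
id: HP:0000939
name: Osteoporosis
is_a: HP:0004349 ! Reduced bone mineral density

[Term]
id: HP:0000400
name: Macrotia
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0002265
name: Large fleshy ears
is_a: HP:0000400 ! Macrotia

[Term]
id: HP:0012759
name: Neurodevelopmental abnormality
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0012758
name: Neurodevelopmental delay
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0001249
name: Intellectual disability
is_a: HP:0012759 ! Neurodevelopmental abnormality

[Term]
id: HP:0000708
name: Behavioral abnormality
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:9000006
name: Hyperactivity (toy)
is_a: HP:0000708 ! Behavioral abnormality

[Term]
id: HP:0002360
name: Sleep disturbance
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:9000005
name: Insomnia (toy)
is_a: HP:0002360 ! Sleep disturbance

[Term]
id: HP:0000366
name: Abnormality of the nose
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0000431
name: Wide nasal bridge
is_a: HP:0000366 ! Abnormality of the nose

[Term]
id: HP:0000448
name: Prominent nose
is_a: HP:0000366 ! Abnormality of the nose

[Term]
id: HP:9000004
name: Broad nasal tip (toy)
is_a: HP:0000366 ! Abnormality of the nose

[Term]
id: HP:0100737
name: Abnormal hard palate morphology
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0000202
name: Oral cleft
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0000175
name: Cleft palate
alt_id: HP:9000175
is_a: HP:0100737 ! Abnormal hard palate morphology
is_a: HP:0000202 ! Oral cleft

[Term]
id: HP:0000204
name: Cleft upper lip
is_a: HP:0000202 ! Oral cleft

[Term]
id: HP:9000002
name: Median cleft lip and palate (toy)
is_a: HP:0000175 ! Cleft palate

[Term]
id: HP:9000003
name: Cleft lip (toy)
is_a: HP:0000202 ! Oral cleft

[Term]
id: HP:9000007
name: Axillary pterygium (toy)
is_a: HP:0001367 ! Abnormal joint morphology

[Term]
id: HP:9000008
name: Joint hypermobility (toy)
is_a: HP:0001367 ! Abnormal joint morphology

[Term]
id: HP:9000009
name: Abnormality of the Achilles tendon (toy)
is_a: HP:0100261 ! Abnormal tendon morphology

[Term]
id: HP:9000010
name: obsolete Palate cleft (toy)
is_obsolete: true
replaced_by: HP:0000175

[Term]
id: HP:9000011
name: obsolete Dead end (toy)
is_obsolete: true
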