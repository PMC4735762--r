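species	group	exon_present	ss6	pwms6	ss7	pwms7	observed_skipping
Human	therian	TRUE	UCAAA|GUAAGUGA	8.6625	AGGGG|GUAAGAGC	5.0898	alternative
Chimpanzee	therian	TRUE	UCAAA|GUAAGUCA	9.0200	AGGGG|GUAAGAGC	5.0898	alternative
Mouse	therian	TRUE	UCAAA|GUAAGUGA	9.5187	AGGGG|GUAAGAAC	5.5747	alternative
Rat	therian	TRUE	UCAAA|GUAAGUGA	9.3740	AGGGG|GUAAGAAC	5.5747	alternative
Cow	therian	TRUE	UCAAA|GUAAGUGA	9.1264	AGGGG|GUAAGAGC	5.0898	alternative
Dog	therian	TRUE	UCAAA|GUAAGUGA	9.1264	AGGGG|GUAAGAGC	5.5361	alternative
Shrew	therian	TRUE	ACAAA|GUAAGUGG	9.3351	CGGGG|GUAAGCGC	6.5608	alternative
Armadillo	therian	TRUE	CCAAA|GUAAGUCA	9.7922	AGGGG|GUAAGAGC	5.5361	alternative
Opossum	therian	TRUE	UCCAA|GUAAGUGA	9.9648	AGGGG|GUAAGAGC	4.6637	alternative
Platypus	monotreme	TRUE	UCAAA|GUAAGGGA	8.3157	CGGGG|GUAAGAGC	4.8212	constitutive
Chicken	bird	TRUE	GCAAA|GUAAGAGU	5.6036	AGGGG|GUAAGAGC	5.9924	constitutive
Zebrafish	fish	TRUE	UCAAA|GUAUGUCC	7.9026	AACAG|GUCAGCUU	8.1978	constitutive
Turtle	reptile	TRUE	ACAAA|GUAAGCAU	10.6407	GGGGG|GUAAGACC	3.8889	alternative
Frog	amphibian	TRUE	ACAAA|GUGAGUAU	8.5266	AAAGG|GUAACUAU	6.4370	constitutive_inferred
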