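subject_id	cohort	age_years	sex	ethnicity	clinical_flags	urine_ghb	ghb_reported_abnormal	imaging_suggestive	allele1	allele2	hgvs_p1	hgvs_p2	class1	class2
case_01	BG-BCM	0.5	M	Middle Eastern	developmental_delay;hypotonia		TRUE		c.668G>A	c.668G>A	p.Cys223Tyr	p.Cys223Tyr	pathogenic	pathogenic
case_02	BG-BCM	0.5	M		developmental_delay;hypotonia;failure_to_thrive		TRUE		c.1597G>A	c.1015-2A>C	p.Gly533Arg		pathogenic	pathogenic
case_03	BG-BCM	1	F	South Asian	developmental_delay;hypotonia				c.768_784del	c.768_784del	p.Ile257GlufsTer12	p.Ile257GlufsTer12	pathogenic	pathogenic
case_04	BG-BCM	1	F		developmental_delay;hypotonia		TRUE	TRUE	c.649G>A	c.649G>A	p.Ala217Thr	p.Ala217Thr	pathogenic	pathogenic
case_05	BG-BCM	1	F	Hispanic American	developmental_delay;hypotonia		TRUE		c.379_380del	c.379_380del	p.Trp127ValfsTer8	p.Trp127ValfsTer8	pathogenic	pathogenic
case_06	BG-BCM	1	F		developmental_delay;hypotonia		TRUE	TRUE	c.1226G>A	c.1323dup	p.Gly409Asp	p.Pro442AlafsTer19	pathogenic	pathogenic
case_07	BG-BCM	2	M	Asian	seizures;microcephaly;hypotonia;developmental_delay				c.1501_1503del	c.1501_1503del	p.Glu501del	p.Glu501del	pathogenic	pathogenic
case_08	BG-BCM	4	F	European	speech_delay;developmental_delay		TRUE		c.967_968dup	c.1597G>A	p.Gln323HisfsTer4	p.Gly533Arg	pathogenic	pathogenic
case_09	BG-BCM	5	M	Hispanic	developmental_delay;ataxia;hypotonia;speech_delay			TRUE	c.111_122delinsG	c.608C>T	p.Ala38GlyfsTer94	p.Pro203Leu	pathogenic	pathogenic
case_10	BG-BCM	7	F		stroke		TRUE	TRUE	c.416C>A	c.1015-2A>C	p.Ala139Asp		pathogenic	pathogenic
case_11	BG-BCM	10	M	European	developmental_delay;hypotonia		TRUE		c.612G>A	c.1234C>T	p.Trp204Ter	p.Arg412Ter	pathogenic	pathogenic
case_12	BG-BCM	11	F	African American	developmental_delay		TRUE		c.380G>A	c.431C>A	p.Trp127Ter	p.Ala144Asp	pathogenic	pathogenic
case_13	BG-BCM	12	F	European	developmental_delay;hypotonia		TRUE		c.612G>A	c.1234C>T	p.Trp204Ter	p.Arg412Ter	pathogenic	pathogenic
case_14	BG-BCM	22	F	European	known_ssadhd				c.803G>A	c.1558G>C	p.Gly268Glu	p.Gly520Arg	pathogenic	pathogenic
case_15	BG-BCM	25	F	European	known_ssadhd				c.803G>A	c.1558G>C	p.Gly268Glu	p.Gly520Arg	pathogenic	pathogenic
case_16	BG-BCM	44	M	European	developmental_delay;hypotonia;seizures;autistic_features				c.1597G>A	c.1234C>T	p.Gly533Arg	p.Arg412Ter	pathogenic	pathogenic
case_17	Biobank	2	F		known_ssadhd	4323.0			c.612G>A	c.1597G>A	p.Trp204Ter	p.Gly533Arg	pathogenic	pathogenic
case_18	Biobank	5	M		known_ssadhd	431.4			c.104_127del	c.1015-2A>C	p.Ser35Ter		pathogenic	pathogenic
case_19	Biobank	7	F		known_ssadhd	228.0			c.612G>A	c.803G>A	p.Trp204Ter	p.Gly268Glu	pathogenic	pathogenic
case_20	Biobank	10	F		known_ssadhd	302.0			c.608C>T	c.608C>T	p.Pro203Leu	p.Pro203Leu	pathogenic	pathogenic
case_21	Biobank	11	F		known_ssadhd	1431.0			c.1226G>A	c.1323dup	p.Gly409Asp	p.Pro442AlafsTer18	pathogenic	pathogenic
case_22	Biobank	25	M		known_ssadhd	74.5			c.754G>T	c.754G>T	p.Gly252Cys	p.Gly252Cys	pathogenic	pathogenic
case_23	Biobank	27	M		known_ssadhd	81.2			c.612G>A	c.612G>A	p.Trp204Ter	p.Trp204Ter	pathogenic	pathogenic
case_24	Biobank	41	M		known_ssadhd	60.8			c.612G>A	c.1015-2A>C	p.Trp204Ter		pathogenic	pathogenic
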