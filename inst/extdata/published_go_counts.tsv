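term	description	N	B	n	b	q
GO:0004984	olfactory receptor activity	17424	362	151	24	3.35e-11
GO:0004930	G-protein coupled receptor activity	17424	788	151	26	7.86e-06
GO:0004888	transmembrane signalling receptor activity	17424	1154	151	28	8.29e-04
GO:0004872	receptor activity	17424	1464	151	32	8.60e-04
GO:0038023	signalling receptor activity	17424	1253	151	28	2.50e-03
GO:0004871	signal transducer activity	17424	1548	151	28	9.62e-02
GO:0060089	molecular transducer activity	17424	1548	151	28	8.25e-02
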