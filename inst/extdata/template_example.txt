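Volume	UV 280	UV 260	Fraction	
ml	mAU	mAU	ml	(Fractions)
0	0	0	0.5	A1
0.5	1	0.6	1	A2
1	2	1.2		
1.5	1	0.6		
2	0	0		
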