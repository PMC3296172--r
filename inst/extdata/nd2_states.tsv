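#locus	ND2
#ref	D. obscura
#species	D. lini	7	non-monophyletic
#species	D. ohnishii	4	non-monophyletic
#species	D. ogumai	2	monophyletic
position	region	kind	D. lini	D. ohnishii	D. ogumai
114	ND2	substitution	R	A	G
155	ND2	substitution	T	T	C
342	ND2	substitution	C	C	T
345	ND2	substitution	A	A	R
408	ND2	substitution	Y	C	T
411	ND2	substitution	A	A	G
434	ND2	substitution	G	G	A
487	ND2	substitution	S	S	G
543	ND2	substitution	T	T	C
552	ND2	substitution	A	R	A
667	ND2	substitution	W	A	A
669	ND2	substitution	W	A	A
747	ND2	substitution	R	G	G
781	ND2	substitution	T	T	C
796	ND2	substitution	C	C	T
829	ND2	substitution	M	A	A
895	ND2	substitution	C	C	T
900	ND2	substitution	T	T	C
934	ND2	substitution	C	C	T
954	ND2	substitution	C	C	T
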