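# token<TAB>pos<TAB>gold[<TAB>pred][<TAB>bits]; 0-based tokens
Abdomen	VBN	192	000000,000000,000011,000000
is	VBZ	0	000000,000000,000000,000000
soft	NN	0	000000,000000,000000,000000
,	.	0	000000,000000,000000,000000
nontender	NN	8192	000000,000010,000000,000000
,	.	0	000000,000000,000000,000000
nondistended	VBN	4	000000,000000,000000,000100
,	.	0	000000,000000,000000,000000
negative	JJ	0	000000,000000,000000,000000
bruits	NNS	4096	000000,000001,000000,000000
.	.	0	000000,000000,000000,000000

The	DT	0	000000,000000,000000,000000
tricuspid	NN	64	000000,000000,000001,000000
valve	NN	0	000000,000000,000000,000000
leaflets	NNS	262144	000001,000000,000000,000000
are	VBP	0	000000,000000,000000,000000
mildly	RB	0	000000,000000,000000,000000
thickened	VBN	4096	000000,000001,000000,000000
.	.	0	000000,000000,000000,000000

There	EX	0	000000,000000,000000,000000
is	VBZ	0	000000,000000,000000,000000
a	DT	0	000000,000000,000000,000000
small	NN	0	000000,000000,000000,000000
amount	NN	0	000000,000000,000000,000000
of	IN	0	000000,000000,000000,000000
blood	NN	192	000000,000000,000011,000000
seen	VBN	0	000000,000000,000000,000000
within	IN	0	000000,000000,000000,000000
the	DT	0	000000,000000,000000,000000
third	NN	262144	000001,000000,000000,000000
and	CC	0	000000,000000,000000,000000
fourth	NN	524288	000010,000000,000000,000000
ventricles	NNS	12288	000000,000011,000000,000000
.	.	0	000000,000000,000000,000000

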