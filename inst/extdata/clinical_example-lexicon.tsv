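abdomen	0
is	4
soft	0
,	8
nontender	9
nondistended	3
negative	1
bruits	9
.	0
the	7
tricuspid	6
valve	3
leaflets	8
are	4
mildly	3
thickened	9
there	1
a	2
small	8
amount	8
of	3
blood	4
seen	4
within	3
third	1
and	7
fourth	2
ventricles	9
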