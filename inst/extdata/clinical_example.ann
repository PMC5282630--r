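T1	Disorder 0 7;51 57	Abdomen bruits
T2	Disorder 0 7;17 26	Abdomen nontender
T3	Disorder 28 40	nondistended
T4	Disorder 63 72;79 87;99 108	tricuspid leaflets thickened
T5	Disorder 137 142;159 164;176 186	blood third ventricles
T6	Disorder 137 142;169 186	blood fourth ventricles
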