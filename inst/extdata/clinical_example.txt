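Abdomen is soft, nontender, nondistended, negative bruits.
The tricuspid valve leaflets are mildly thickened.
There is a small amount of blood seen within the third and fourth ventricles.
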