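# Ionizable-group pKa values (EMBOSS set). type: acid loses a proton when
# deprotonated-neutral groups would be charged negative; base gains one.
group	type	pka
Nterm	base	8.6
Cterm	acid	3.6
C	acid	8.5
D	acid	3.9
E	acid	4.1
H	base	6.5
K	base	10.8
R	base	12.5
Y	acid	10.1
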