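node	label	x	y	z
ORBmid.L	Left orbital middle frontal gyrus	-30.65	50.43	-9.62
PCL.L	Left postcentral gyrus	-7.63	-25.36	70.07
OLF.R	Right olfactory cortex	10.43	15.91	-11.26
CAU.L	Left caudate nucleus	-11.46	11	9.24
PUT.R	Right lenticular putamen	27.78	4.91	2.46
OLF.L	Left olfactory cortex	-8.06	15.05	-11.46
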