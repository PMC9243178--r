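name	recognition	cut_top	cut_bottom	class
EcoRI	GAATTC	1	5	palindromic
HindIII	AAGCTT	1	5	palindromic
PstI	CTGCAG	5	1	palindromic
XbaI	TCTAGA	1	5	palindromic
SpeI	ACTAGT	1	5	palindromic
BsaI	GGTCTC	7	11	typeIIS
BbsI	GAAGAC	8	12	typeIIS
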