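# Bjellqvist pKa values for theoretical pI calculation.
# site: Nterm/Cterm or one-letter residue code; charge: pos|neg.
site	pka	charge
Nterm	7.50	pos
Cterm	3.55	neg
C	9.00	neg
D	4.05	neg
E	4.45	neg
H	5.98	pos
K	10.00	pos
R	12.00	pos
Y	10.00	neg
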