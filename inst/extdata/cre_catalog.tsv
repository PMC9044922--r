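# Default cis-regulatory element catalog (literature-standard consensi).
# User-replaceable: any TSV with columns name, consensus (IUPAC), group.
# non_canonical = 1 flags placeholder definitions that are not public.
name	consensus	group	non_canonical
CAAT-box	CCAAT	promoter-related	0
TATA-box	TATA	promoter-related	0
ABRE	ACGTG	hormone-responsive	0
ABRE3a	TACGTG	hormone-responsive	0
As-1	TGACG	hormone-responsive	0
CGTCA-motif	CGTCA	hormone-responsive	0
GARE-motif	TCTGTTG	hormone-responsive	0
AuxRR-core	GGTCCAT	hormone-responsive	0
G-box	CACGTG	light-responsive	0
TCT-motif	TCTTAC	light-responsive	0
GT1-motif	GGTTAA	light-responsive	0
Box4	ATTAAT	light-responsive	0
MRE	AACCTAA	light-responsive	0
MBS	CAACTG	environmental-stress	0
DRE-core	RCCGAC	environmental-stress	0
LTR	CCGAAA	environmental-stress	0
ARE	AAACCA	environmental-stress	0
TC-rich_repeats	GTTTTCTTAC	environmental-stress	0
CAT-box	GCCACT	development	0
O2-site	GATGACATGG	development	0
GCN4_motif	TGAGTCA	development	0
circadian	CAAAGATATC	development	0
W-box	TTGACC	site-binding	0
AT-rich_element	TAAAATAT	site-binding	0
MYB	TAACCA	other	0
MYC	CATTTG	other	0
STRE	AGGGG	other	1
Unnamed-4	CTCC	other	1
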