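# gfam

Desk-scale genome-wide analysis of the plant **AP2/ERF transcription-factor
superfamily**, built around the heat-stress candidate-gene workflow used in
bread wheat (*Triticum aestivum*): identify family members by DNA-binding
domain architecture, characterise them biochemically and structurally, call
gene duplications, build phylogenies, scan promoters for cis-regulatory
elements, and categorise heat-tolerance candidate genes from qPCR expression
in contrasting (tolerant vs susceptible) genotypes.

It is intended for plant molecular biologists and breeders who want a
reproducible, fully testable version of this common gene-family survey: every
stage also runs on synthetic inputs with planted ground truth, so the whole
pipeline can be validated without downloading a reference genome.

## What it computes

**Family classification.** Proteins are scanned against bundled
position-specific scoring profiles for the AP2 and B3 domains (a lightweight,
user-replaceable stand-in for an HMM domain search; profiles are plain TSV
files).  Architecture determines the family:

* 1 AP2 domain → ERF/DREB family,
* 2 AP2 domains → AP2 family,
* 1 AP2 + 1 B3 domain → RAV family,
* no well-defined AP2 domain → discarded.

Single-AP2 proteins are sub-classified by the residues at AP2-domain
alignment positions 14 and 19: Val14/Glu19 is evidence for **DREB**,
Ala14/Asp19 for **ERF**; conflicting or absent evidence falls into *others*.
The conserved WLG residue triple is catalogued per protein (variants such as
WIG, WID, GLG mark divergent members).

**Protein properties.** Length, molecular weight (average masses), theoretical
isoelectric point (Henderson–Hasselbalch bisection over the Bjellqvist pKa
set) and GRAVY (mean Kyte–Doolittle hydropathy).

**Duplications.** Needleman–Wunsch global alignment with BLOSUM62; identity,
similarity (BLOSUM62 > 0) and coverage are percentages of the *longer*
sequence.  A pair is a **segmental duplicate** when coverage > 90% *and*
identity > 90%; a segmental pair on one chromosome, one gene following the
other within 100 kb, is a **tandem duplicate**.

**Phylogeny.** Pairwise-deletion p-distances, Saitou–Nei neighbor joining
(deterministic tie-breaks, ape-compatible trees), column-bootstrap support.

**Promoter elements.** IUPAC consensus scanning of 2-kb promoters on both
strands against an editable catalog grouped into the seven standard
functional classes (light-, hormone-, stress-responsive, development,
promoter-related, site-binding, other).

**Expression.** Relative expression by 2<sup>−ΔΔCt</sup> against a
housekeeping gene; per-class fold change FC (mean of linear ratios) and
Log2FC (mean of per-replicate log2 ratios); a gene is significantly up/down
when Log2FC ≥ 1 / ≤ −1.  Genes are grouped by the sign pattern across the
two genotype classes and categorised into heat-tolerance traits
(*highly / moderately highly / heat-tolerant*, the susceptible mirror,
*neutral*, *not-DE*).

**Phenotype.** Heat damage index HDI = 100 × (mean control − mean heat root
depth)/mean control, with a Welch test between tolerance classes.

## Worked example

Classify the bundled reference panel of 18 differentially expressed wheat
AP2/ERF genes measured in two heat-tolerant and two heat-susceptible
genotypes:

```r
library(gfam)
panel <- read_reference_panel()
calls <- expression_calls(panel[, c("gene", "log2fc_tolerant",
                                    "log2fc_susceptible")])
head(calls, 4)
#>                gene log2fc_tolerant log2fc_susceptible sig_tolerant
#>  TraesCS4D02G298600            2.62              -1.20           UP
#>  TraesCS5D02G317100            1.84              -0.52           UP
#>  TraesCS1A02G221900            1.08              -0.78           UP
#>  TraesCS2D02G515900            1.86               0.15           UP
#>  sig_susceptible group                           trait
#>             DOWN     1            highly heat-tolerant
#>               NS     1 moderately highly heat-tolerant
#>               NS     1 moderately highly heat-tolerant
#>               NS     2                   heat-tolerant
```

The first gene is up-regulated in tolerant genotypes (Log2FC 2.62 ≥ 1) *and*
down-regulated in susceptible ones (−1.20 ≤ −1) — both pieces of evidence
point the same way, so it is called a highly heat-tolerant candidate.

```r
s <- summarize_regulation(calls)
sprintf("tolerant: %d up / %d down; susceptible: %d up / %d down; DEGs: %d",
        s$up_tolerant, s$down_tolerant, s$up_susceptible,
        s$down_susceptible, s$n_deg)
#> "tolerant: 8 up / 5 down; susceptible: 7 up / 4 down; DEGs: 18"
```

Classifying a synthetic proteome with planted domains recovers the planted
truth exactly:

```r
g <- generate_proteome(c(DREB = 3, ERF = 3, AP2 = 1, RAV = 1, decoy = 2),
                       seed = 7)
head(classify_proteome(g$proteins)[, 1:6], 5)
#>  protein_id   family subfamily residue14 residue19 wlg
#>    SYNP0001 ERF_DREB      DREB         V         E WLG
#>    SYNP0002 ERF_DREB      DREB         V         E WLG
#>    SYNP0003 ERF_DREB      DREB         V         E WLG
#>    SYNP0004 ERF_DREB       ERF         A         D WLG
#>    SYNP0005 ERF_DREB       ERF         A         D WLG
```

A thin CLI over the same functions ships as `inst/scripts/gfam`
(subcommands `classify`, `protparam`, `duplicates`, `tree`, `cre`, `qpcr`,
`phenotype`, `summarize`, `simulate`).

## Limitations

The profile scanner reproduces the *classification logic* of an HMM domain
search at desk scale; it is not an HMM engine, and genome-wide gene counts
for real proteomes depend on the profile set supplied.  Multiple sequence
alignment is out of scope: the phylogeny module consumes pre-aligned FASTA.
See the methods vignette (`vignettes/gene-family-heat-analysis.Rmd`) for the
full model description and design rationale.
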