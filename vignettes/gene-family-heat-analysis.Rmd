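---
title: "Gene-family classification and heat-stress expression analysis with gfam"
author: "gfam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family classification and heat-stress expression analysis with gfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfam)
options(gfam.verbose = FALSE)
```

## Scope and model

The AP2/ERF superfamily is one of the largest plant transcription-factor
groups, defined by the ~60-residue AP2 DNA-binding domain.  In hexaploid
bread wheat its members are prime heat-stress candidate genes: family
surveys proceed from domain detection through classification, duplication
analysis, phylogeny and promoter inspection to qPCR validation in
contrasting genotypes.  `gfam` implements that workflow as composable,
tested functions, with a synthetic-data generator that supplies every input
with planted ground truth.

This vignette records the models, the tunable parameters, the numerical
choices and the design decisions taken where the method left room.

## Domain detection and family rules

Domain detection uses one position-specific scoring profile per domain
(AP2, B3).  A profile is a matrix of per-column residue scores plus
metadata: the diagnostic columns 14 and 19, the columns of the conserved
WLG triple, affine gap penalties and a score threshold.  Scanning is local
(Smith–Waterman) alignment of the protein against the profile, iterated:
the best hit above threshold is reported, masked, and scanning repeats (up
to `max_hits`, default 4).  Hits from different profiles are reduced to a
non-overlapping set greedily by score, then leftmost — a deterministic,
input-order-independent rule.

The bundled default profiles are built from 60-column (AP2-like) and
50-column (B3-like) consensus sequences with match score +2 and mismatch
−1, gap open 4 and extend 1 (first gapped position costs the opening
penalty, further positions the extension), and a threshold of half the
perfect-match score (60 and 50 score units respectively).  The threshold
plays the role of the E-value gate of a probabilistic domain search: at
half the maximum score, an exact or lightly diverged domain copy always
clears it while random 20-letter background essentially never does (the
expected per-residue score of random sequence is negative, so local-hit
scores grow only logarithmically with length).  Profiles are plain TSV
files (`inst/extdata/ap2_profile.tsv`), so profiles derived from a real
Pfam alignment can be substituted without code changes; positions "14" and
"19" are 1-based profile columns, matching how these residues are counted
along the domain alignment in the field's literature.

Family assignment is purely architectural: one AP2 domain → ERF/DREB
family; two AP2 → AP2 family; AP2 + B3 → RAV; anything without a
well-defined AP2 hit (including unexpected architectures, with a warning)
is discarded.  Sub-family assignment for single-AP2 proteins counts
evidence at the diagnostic columns — Val14 and Glu19 for DREB, Ala14 and
Asp19 for ERF — and requires strictly more evidence for one sub-family
than the other.  The method's sources do not state how a one-residue-each
conflict (say Val14 with Asp19) was resolved; `gfam` sends every tie,
including the zero-evidence case and columns gapped in the alignment, to
the *others* bucket, which is exactly the role that bucket plays in family
surveys.  The WLG triple is read off the aligned profile columns, with
gaps rendered as `-`.

## Protein properties

Molecular weight is the sum of average (not monoisotopic) residue masses
plus one water — the convention of the standard online protein-analysis
tools whose outputs these surveys report.  The theoretical pI solves
net charge = 0, where the charge is a Henderson–Hasselbalch sum over the
termini and the D, E, C, Y, H, K, R side chains with the Bjellqvist pKa
table (bundled as `inst/extdata/pka_bjellqvist.tsv`, swappable for e.g.
the EMBOSS set).  Charge is monotone decreasing in pH, so bisection on
[0, 14] converges unconditionally; it stops at |charge| < 1e-4 or a
bracket below 1e-3 pH units, and the tests verify agreement with a dense
(0.001-step) grid scan to 0.01.  GRAVY is the plain mean of Kyte–Doolittle
indices, bounded by the table extremes ±4.5.

## Duplication calling

Pairwise global alignment uses BLOSUM62 with gap open 10 / extend 0.5 —
the matrix is prescribed by the workflow, the gap parameters are the
common BLOSUM62 convention (the identity-matrix web services this step
emulates do not publish theirs) and are configurable.  Identity,
similarity and coverage are all normalised by the longer sequence's
length: identity counts identical aligned positions, similarity positions
scoring > 0 in BLOSUM62 (identities included — the standard reading of
"similar residues"), and coverage the longer sequence's residues inside
the aligned region after trimming terminal gaps.

A pair is segmental when coverage > 90 *and* identity > 90 (strict
inequalities, matching the ">90%" phrasing of the rule).  The criterion
pair "coverage and >90% similarity of identity" is read as an identity
threshold — identity is the stricter and standard criterion, and
similarity is still reported for inspection.  Tandem upgrades require the
same chromosome, a gap of at most 100 kb between the nearer gene ends, and
adjacency — no other gene of the analysed set between the two — which
implements "one following the other" deterministically via start-order
ranks.  Distances are computed in the package's internal 0-based half-open
coordinates; GFF3's 1-based inclusive convention is converted exactly once
at the I/O boundary, which keeps the 100-kb rule free of off-by-one
ambiguity.  Tandem calls are by construction a subset of segmental calls,
so both the "127 segmental + 1 tandem" and the "128 total" style of
reporting can be derived from one output table.

All-vs-all scoring is quadratic and intended for within-family sets (tens
to a few hundred sequences), matching how duplicate counts are reported
per family.

## Phylogeny

Distances are pairwise-deletion p-distances (sites with a gap in either
sequence are dropped for that pair); the common default of desktop
phylogeny tools for protein NJ trees, with a Poisson correction
(−log(1−p)) behind a flag.  The tree is Saitou–Nei neighbor joining with
the Studier–Keppler Q-criterion.  Two numerical choices make results
platform-stable: ties in the Q minimisation are broken by the
lexicographically smallest index pair, and negative branch lengths are
clamped to zero.  Trees are returned as `ape` "phylo" objects, serialised
through Newick at full double precision (17 significant digits) so that an
additive input matrix is reproduced exactly (to 1e-9) by the output path
metric — a property the test suite checks on random additive 4–8 taxon
trees, alongside topological agreement with `ape::nj` as an independent
implementation.

Bootstrap support resamples alignment *columns* with replacement, rebuilds
the NJ tree per replicate, and reports for each internal edge of the
point-estimate tree the percentage of replicates containing the same
bipartition.  Replicates in which some pair loses every comparable site
are skipped and logged.  Because resampling is indexed by column only,
supports are invariant to taxon input order.  Multiple sequence alignment
is deliberately out of scope: the module consumes pre-aligned FASTA, and
the synthetic generator emits gap-free alignments so no aligner is needed
to test the stage.

## Promoter cis-regulatory elements

The scanner reports every IUPAC-consensus match of a catalog motif on both
strands of a promoter (a minus-strand hit is a reverse-complement match
reported at its forward offset); overlapping matches are all kept and `N`
never matches.  The catalog is data, not code: the published counts for
this analysis depend on a proprietary database's internal signatures, so
the bundled catalog carries literature-standard consensi (ABRE `ACGTG`,
G-box `CACGTG`, MBS `CAACTG`, DRE-core `RCCGAC`, CAAT-box `CCAAT`, …)
grouped into the seven standard functional classes, with two elements
whose public definitions do not exist (`STRE`, `Unnamed-4`) flagged as
non-canonical placeholders.  For that reason motif *counts* on real
promoters are only as authoritative as the catalog supplied, and absolute
published counts are not reproduced — the scanning and summarising logic
is what the package tests (count conservation, strand symmetry, exact
planted-count recovery).

## qPCR expression and trait categorisation

Relative expression follows 2^−ΔΔCt: ΔCt = Ct_gene − Ct_reference per
sample; the per-genotype baseline is the *mean* control-replicate ΔCt
(replicates are unpaired in a completely randomised design, so
replicate-pairing would be arbitrary); each heat replicate yields
ratio = 2^−ΔΔCt.  Technical repeats, if present, are averaged into one Ct
first.

Averaging order is the one genuinely open point of the analysis: published
FC and Log2FC columns are mutually inconsistent under "Log2FC =
log2(mean FC)" (e.g. a printed FC of 5.94 beside a Log2FC of 1.84, while
log2(5.94) = 2.57).  `gfam` therefore defines FC as the arithmetic mean of
linear ratios (genotype means, then class mean) and Log2FC as the mean of
per-replicate log2 ratios — the only reading consistent with the AM–GM
inequality across all published rows, and the property the test suite
asserts (`Log2FC ≤ log2(FC)` always).

Significance is threshold-based, |Log2FC| ≥ 1 with inclusive boundaries.
Regulation groups are sign patterns over the (tolerant, susceptible) pair,
with zero counting as up — the choice that makes the published small
positive values (0.04, 0.07) land in the up-regulated groups they are
listed under.  The trait rule scores evidence: tolerant-UP and
susceptible-DOWN are tolerance evidence, the mirror pair susceptibility
evidence; two pieces → *highly*, one piece via class-UP → *moderately
highly* when the other class trends opposite, plain otherwise; evidence on
both sides → *neutral*; none → *not-DE*.  This rule is a reconstruction
from the 18 published example rows; cells the examples never exercise
(e.g. tolerant-DOWN with a susceptible value in (−1, 0]) are filled by
symmetry.  It is total over the real plane and reproduces all 18 published
labels and the footer counts (8/5 tolerant, 7/4 susceptible, 18 DEGs).

## Phenotype

The heat damage index is defined here as the relative root-depth reduction
HDI = 100·(mean control − mean heat)/mean control per genotype, averaged
over genotypes per class — the source workflow uses the term without a
formula, so this definition is the package's own and is recorded as such.
It is scale-invariant (units cancel).  The class contrast is a two-sided
Welch t-test on replicate-level HDI values (Satterthwaite df); the
degenerate zero-variance-both-classes case returns p = 1 for equal means.
A multiple-comparison letter display across genotypes is out of scope.

## The synthetic-data generator

Each generator is a pure function of its parameters and a seed; a root
seed fans out to named substreams (`derive_seed`), so adding a generator
never perturbs another's fixtures.  Defaults mirror the study design the
package targets: 2 tolerant + 2 susceptible genotypes × 2 treatments × 3
replicates for qPCR (reference gene constant at Ct 20, control ΔCt drawn
once per gene and genotype in 2–8 cycles, replicate noise applied to heat
replicates), control root depths around 100 mm with class HDIs of 30 and
65 (a 35-point class difference), 2-kb promoters, duplicate pairs with an
*exact* number `round(rate × length)` of substituted sites so identity is
100·(1 − rate) percent deterministically, and tandem gaps drawn below
100 kb (a fixed gap, e.g. 2.51 kb, can be requested).

Two constructions make zero-noise recovery exact rather than
probabilistic.  Proteome backgrounds are rejection-sampled to contain no
domain hit, and each assembled protein is re-scanned so the planted
(domain, offset) set is recovered identically before it is emitted.
Promoter backgrounds are iteratively repaired: the full catalog is
scanned, any hit not contained in a planted instance has its background
bases resampled, and the loop runs until the scan reports planted
instances only.  Planted truth therefore equals the scan output exactly
when plan motifs do not contain one another; palindromic consensi yield
one hit per strand at the planted offset, and the truth table records the
final attributable counts.

What the generator does *not* emulate: real domain divergence (planted
copies differ from consensus only at the controlled columns), indel
evolution in duplicate pairs (substitutions only), realistic promoter base
composition (uniform background), amplification-efficiency variation in
qPCR, and genome-scale gene density.  Passing the planted-truth tests
therefore demonstrates the correctness of the pipeline's logic, not
genome-wide sensitivity on real data — on a real proteome the recall of
the domain scan depends on the profile set supplied.

## Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path while keeping the whole suite fast on a laptop: a 200-protein
synthetic proteome for classification recovery, 100 random 4–8 taxon
additive trees for NJ, 4 duplicate pairs at 5% and 15% divergence, 200
simulated Ct tables at 0.2-cycle noise for parameter recovery (the grand
mean is required to fall within three standard errors of the planted
value), 100 random peptides for the pI cross-check, and 4 promoters × 4
motifs for count recovery.  All are regenerated from the seed at run
time; no binary fixtures are stored.

## Known limitations

* The profile scanner reproduces classification logic, not HMM
  statistics; E-values are not computed and Pfam-calibrated sensitivity is
  not claimed.
* Genome-wide counts for a real proteome (family sizes, duplicate-pair
  totals, per-chromosome distributions, promoter-element totals) depend on
  external inputs — the reference proteome, a real domain profile and a
  complete motif catalog — and are therefore not asserted by the package's
  tests, although the pipeline supports re-running them.
* Ka/Ks dating, synteny-aware duplication classification, de novo motif
  discovery and maximum-likelihood phylogenetics are out of scope.
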