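---
title: "Methods: aquaporin family annotation, substrate inference and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aquaporin family annotation, substrate inference and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpscan)
```

# Scope and data model

`aqpscan` covers the desk-scale part of a genome-wide aquaporin family
survey: everything that can be computed from sequences, gene models, Ct
tables and the family's printed reference tables. The package ships the
sweet cherry (*Prunus avium*) family as plain-text fixtures — a 28-member
roster of motif signatures and physicochemical lookups, the per-substrate
SDP (specificity-determining position) table, and the per-gene presence
lists of nine stress-related promoter elements. Genome mining,
maximum-likelihood phylogenetics, synteny maps, HMM topology prediction
and subcellular-localization predictors are deliberately out of scope; the
roster carries the latter two as lookup columns only.

# Motif annotation by position templates

The family's motif vocabulary (NPA I/II, the ar/R filter residues H2, H5,
LE1, LE2, Froger's P1–P5, and nine SDP columns per substrate) is defined
relative to a multiple alignment in the source literature, which never
publishes absolute coordinates. The package's answer to that gap is the
*position template*: one synthetic reference per subfamily with a fixed,
documented column layout (`template_layout()`), built deterministically so
it is identical across machines. Annotation of a query is then:

1. global alignment of the query against the subfamily reference
   (Needleman–Wunsch via Biostrings, BLOSUM62, gap open 10, gap extend 0.5
   — the common protein defaults; the wildcard `X` is rescored to 0 against
   everything so masked residues are neutral);
2. mapping of each template column through the alignment; columns landing
   on a gap are reported *missing* rather than guessed;
3. an identity floor (default 25% over aligned columns) below which the
   mapping is refused with the observed identity attached, so junk queries
   produce a flagged error instead of a silently wrong annotation.

Because the references are synthetic, mapped annotations are only
meaningful for sequences generated from (or resembling) those backbones;
for real proteins of a new genome a user would substitute templates built
from a curated alignment via `position_template()`. This is a deliberate
design decision, not a limitation of the machinery.

NPA motifs are found primarily by the degenerate grammar
`N-P-[A/S/T/L/V/I]`, which covers every variant in the packaged roster
except the heavily degenerate XIP-type `SLV`/`SPA` pair; when fewer than
two grammar hits exist, template-mapped NPA columns recover those. The
first motif reported is labelled loop B, the second loop E. Because the
grammar requires `N-P`, two regex hits can never overlap; overlap
filtering only matters for template-recovered hits.

## Physicochemical calculators

Molecular weight uses ExPASy-style average residue masses plus one water,
reported in kDa. GRAVY is the arithmetic mean of Kyte–Doolittle values.
The isoelectric point is the bisection root (tolerance 0.001 pH) of the
Bjellqvist net-charge curve, with residue-specific terminal pKa values
where that set defines them. All constants live in
`inst/extdata/physchem_constants.yaml` and can be overridden per call —
note that single-letter residue keys must stay quoted in YAML, since bare
`Y`/`N` parse as booleans. The transmembrane predictor is a hydropathy
heuristic (window 19, threshold 1.6, merged maximal windows): 19 residues
is a typical helix span and 1.6 is the conventional Kyte–Doolittle cutoff
for putative transmembrane segments. It intentionally does not attempt to
reproduce HMM-based domain counts; the roster's printed counts are carried
as a lookup column instead.

# Subfamily classification

The five-subfamily call uses Froger's residues only, in a fixed decision
tree: `P5 != W` is NIP (roster NIPs end in I/L/V/F); among `P5 = W`,
`P4 = F` splits PIP (`P1` in {E, Q}) from XIP (`P2 = C`), and `P4 = Y`
splits TIP (`P1` in {T, V}) from SIP. On the packaged roster this resolves
all 28 members by signature, reproducing the printed 7 PIP / 8 NIP /
8 TIP / 3 SIP / 2 XIP tallies. Signatures outside the tree fall back to a
nearest-canonical-signature call over Froger + ar/R residues, explicitly
flagged `fallback` so downstream code can treat it as low confidence.

# SDP substrate inference

Each substrate's consensus is a list of nine allowed-residue sets; the
engine reports, per protein, the mismatch count and the mismatching SDP
positions. What mismatch count still counts as "a transporter" is never
stated in the family literature — surveys routinely classify members while
noting one or two substitutions. The package therefore defaults to the
strict reading (tolerance 0) and exposes tolerance as a parameter (scalar
or per-substrate named vector); the mismatch report is always emitted so a
tolerant call can be audited. Classification is monotone in tolerance by
construction.

# Promoter element scanning

The element catalog is a YAML file of IUPAC consensus strings. The source
survey names the elements but not their consensus sequences, so the
shipped catalog uses PlantCARE-convention defaults (e.g. ARE `AAACCA`,
STRE `AGGGG`, LTR `CCGAAA`, MBS `CAACTG`); these are editable defaults,
not recovered ground truth. Matching is exact-set IUPAC on both strands;
promoter `N` never matches. Coordinates are 0-based forward-strand
leftmost positions; a minus-strand hit means the element's reverse
complement occupies the window, which makes the hit set invariant under
reverse-complementing a promoter up to the transform
`p -> L - p - len`.

# Gene structure and Ka/Ks

Gene models follow the GFF3 1-based inclusive convention; introns are
derived as inter-exon gaps, so single-transcript models always satisfy
`introns = exons - 1`. UTRs, when annotated as distinct features, are
carried for display and excluded from exon statistics. Cohort extrema are
tie-broken by input order.

Ka/Ks is Nei–Gojobori (1986): per-codon synonymous site fractions averaged
over both sequences; differences counted over minimal mutational pathways,
with multi-hit codons averaged uniformly over orderings and
stop-containing intermediates dropped first (uniform weight over all
orderings in the degenerate case where every ordering hits a stop); and
the Jukes–Cantor transform `d = -3/4 ln(1 - 4/3 p)` applied to both
proportions, with an explicit error at `p >= 3/4`. A site-counting
convention worth noting: a change producing a stop codon counts as
nonsynonymous, which keeps `n_sites + s_sites = 3 x codons` exactly. The
estimator is a documented stand-in for the unspecified web tool used in
the source survey; printed per-gene ratios are treated as fixture data and
only the purifying-selection bound (< 1) is expected to reproduce.

# Expression analysis

Relative quantification is the Pfaffl model
`ratio = E_t^dCt_t / E_ref^dCt_ref` with `dCt = Ct(calibrator) -
Ct(sample)` and efficiencies in (1, 2]; with both efficiencies at 2 it
reduces exactly to `2^ddCt`. Replicate Ct values are averaged
arithmetically per (gene, sample) before ratios — with balanced technical
duplicates this equals the two-stage technical-then-biological mean. The
source protocol names the 0 h baseline as calibrator in one place and the
6 h control in another; the calibrator is therefore an explicit argument,
with the convention that the package's generator uses the first sample.
Not-detected cells are masked `NA`, never imputed as zero, and masked
cells are excluded from every downstream statistic. Regulation calls use a
configurable |log2FC| cutoff (default 1, i.e. 2-fold — the survey plots an
up/down dichotomy without stating one) with closed boundaries. Profile
clustering is average linkage on a pairwise-complete Euclidean distance
(root of summed squared differences over shared unmasked cells, no
rescaling); profiles with fewer than 2 shared cells against every other
profile are excluded with a warning.

# Synthetic data: what it emulates, and what it does not

The generators produce every input format with planted ground truth:

* **Proteins** — subfamily backbones carrying a member's printed
  signatures, spacers mutated at rate 0.15 (high enough to make members
  distinct, low enough that template alignment stays reliable), up to 5
  random insertions to exercise coordinate mapping, and a scrub pass so
  planted NPA motifs are the only degenerate matches. A `-` in an ar/R
  signature becomes a true deletion. Defaults generate the 28 roster
  members with their printed signatures.
* **Promoters** — 2000-bp backgrounds made motif-free on both strands by
  iterative hit-breaking (uniform A/C/G/T composition; a GC-bias knob is
  out of scope), then exactly one planted instance per TRUE presence cell
  at a random offset and strand, re-validated by rescanning. This makes
  per-element gene counts exactly recoverable from the published presence
  lists.
* **Gene models** — exon counts 1–5 (0–4 introns, the family's observed
  range) with exon/intron lengths drawn uniformly from ranges bracketing
  the printed extremes (33–792 bp exons, 91–3450 bp introns).
* **CDS pairs** — one base change per mutated codon, never creating a
  stop; defaults (8 synonymous + 1 nonsynonymous over 100 codons) emulate
  purifying selection.
* **Ct tables** — 3 biological x 2 technical replicates (the survey's
  design), efficiency 2, Gaussian Ct noise with sd 0.2 cycles (a typical
  qPCR technical spread; the survey does not publish one), planted log2
  fold-changes drawn from ±3 unless supplied.

What passing recovery tests show is that the *pipeline* is internally
consistent — planted truths survive the full generate → write → read →
annotate cycle. They do not show that real aquaporins are annotated
correctly: real sequences have correlated composition, unequal motif
spacing, alternative transcripts and alignment ambiguity that the
generators do not model, and real promoters are far from uniform-random.
Problem sizes in the shipped suite (28-member rosters, 2000-bp promoters,
8-codon oracle pairs, 100-seed recovery loops) were chosen as the smallest
sizes that exercise every code path convincingly.

# Known limitations

* Template-based annotation presumes a trustworthy subfamily reference;
  the packaged synthetic templates only anchor the generators and tests.
* The CRE catalog's consensus strings are conventions, not recovered from
  the survey; counts on real promoters depend entirely on that choice.
* NG86 underestimates rates under strong transition/transversion bias; no
  codon-model alternative is provided.
* Distance-based grouping (p-distance + neighbor joining) is plumbing for
  desk-scale determinism, not a substitute for likelihood phylogenetics,
  and no bootstrap is implemented.
* Printed Mw/pI/GRAVY/TDP values for the real cherry proteins require the
  genome's sequences and are carried as fixture columns, not recomputed.
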