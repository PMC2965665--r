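---
title: "Methods: COI barcoding-gap analysis for marine nematodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI barcoding-gap analysis for marine nematodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `nemabar`, and what the synthetic datasets do and
do not establish about real data.

## The problem

Free-living marine nematodes are identified morphologically by few
specialists; DNA barcoding with the mitochondrial COI gene promises a
scalable alternative, but three obstacles recur: (i) COI amplification
in this group is unreliable, so primer sets must be compared; (ii)
sequence datasets are polluted by nuclear copies of mitochondrial
genes (numts, typically pseudogenized) and by contaminants
(bacteria or other metazoans amplified instead of the target); and
(iii) threshold-based identification only works if intraspecific
divergences are cleanly separated from interspecific ones — the
"barcoding gap". The package implements the desk side of such a
survey: in-silico PCR, sequence QC, K2P distance analysis, NJ trees
and gap/threshold analysis, exercisable end to end on simulated data.

## Distance model

Pairwise distances use the Kimura-2-parameter model,
`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`, with *pairwise deletion*: for
each pair, only sites where both sequences carry an unambiguous base
are compared. Pairwise (not complete) deletion is what makes
fragments of unequal length (e.g. 367–393 nt) comparable, and matches
the default of the distance software this style of survey is run in.
K2P is knowingly not an optimal substitution model here; it is used
because it is the de-facto standard for barcode distances, keeping
results comparable across surveys.

Saturated pairs — where `1-2P-Q <= 0` or `1-2Q <= 0` — have no K2P
distance. They are reported `NA`, listed in an exclusion table, and
left out of all distance summaries and histograms rather than clamped
to an arbitrary maximum. One exception is tree-based QC (below).

Per-codon-position distances restrict counting to one codon position
of a single reading frame shared by the whole alignment, determined
from the alignment's majority-rule consensus (`alignment_frame()`):
the fragments are a single protein-coding gene, so one frame per
alignment is the biologically correct choice and is robust to
individual pseudogenes. Third-position distances routinely approach
the edge of the K2P domain; maxima among near-saturated pairs are
then inflated (a pair just inside the domain can yield a distance of
10+ substitutions/site). The reported ranges are honest values of the
estimator, not divergence-time estimates.

## Neighbor joining

`nj_tree()` is the standard Saitou–Nei agglomeration minimising
`Q(i,j) = (n-2) d(i,j) - R_i - R_j`. Two conventions make trees
reproducible and robust:

* ties in the Q matrix are broken by the lexicographically smallest
  pair of cluster labels (a cluster is labelled by its smallest leaf
  id), so the tree does not depend on input order;
* negative branch lengths are clamped to zero with the deficit moved
  to the sibling edge, preserving path lengths.

Trees are unrooted, serialized with a trifurcating root; Newick
output carries 6-decimal branch lengths and quotes labels containing
spaces or metacharacters.

## Quality control

The QC pipeline runs, in order: translation checks, indel detection,
composition screen, then tree-based flags.

**Translation checks.** All rows are translated under the
invertebrate mitochondrial genetic code (NCBI table 5: TGA→Trp,
AGA/AGG→Ser, ATA→Met; stops TAA/TAG only) in the alignment consensus
frame. Any internal stop codon flags `stop_codon`. `frameshift` is
flagged when the best frame retains internal stops or an alignment
gap run has length not divisible by 3 — the two signatures inspected
when screening for pseudogenes. Codons containing ambiguity codes
translate to `X` and never count as stops (conservative; avoids
false numt calls). The nematode-specific codon reassignments
occasionally discussed for this phylum are not implemented; they are
unlikely to affect stop-codon screening.

**Indels.** In the amino-acid alignment, a column is
consensus-residue (consensus-gap) when more than half the rows hold a
residue (gap); a row gapping a consensus-residue run is a deletion, a
row with residues across a consensus-gap run an insertion. An indel
alone is a *warning*, not fatal: in-frame indels occur in genuine
nematode COI, and removing every indel-bearing sequence would discard
real taxa.

**Composition screen.** Sequences whose GC fraction deviates from the
set median by more than 0.15 (absolute) are flagged. This is the
package's database-free stand-in for a similarity search against a
reference database: the nematode mitochondrial fragment is strongly
AT-rich, while typical contaminants (e.g. proteobacteria) are not.
The margin of 0.15 is wide enough that genuine compositional drift
among nematode COI sequences (a few percentage points) never fires
it, while a bacterial insert (GC ≈ 0.55 vs ≈ 0.30) exceeds it by a
wide margin. The screen cannot identify a contaminant whose
composition mimics the target; that case is left to the tree flags.

**Tree flags.** A leaf is `long_branch` when its terminal branch
exceeds 3× the median terminal branch length, and additionally a
`taxonomic_outlier` when its nearest leaf by path length belongs to a
different higher taxon. Removal requires *both* (the joint
`tree_outlier` check): long branches alone can reflect insufficient
taxon sampling rather than artifacts, so a long-branched but
taxonomically coherent leaf is kept. Because trees need a complete
matrix, saturated pairs are filled for this step only with 1.5× the
largest finite distance, scaled further by the pair's raw mismatch
fraction — a constant fill would tie large parts of the matrix and
produce degenerate NJ geometry. The fill can only lengthen an
artifact's branch, and filled pairs remain excluded from every
distance statistic.

Default fatality: `stop_codon`, `frameshift`, `composition_outlier`
and `tree_outlier` remove a sequence; `indel` warns. Every removal is
logged with its reasons.

Two practical caveats. First, the tree flags are *relative*
statistics (median-based), so re-running QC on a filtered set can
newly flag sequences whose close relatives were removed in the first
pass; the pipeline is designed as a single pass, and idempotence
holds on artifact-free data. Second, when several contaminants are
present they attract each other in the tree (classic long-branch
attraction), and a contaminant absorbed into such a cluster can show
a short terminal branch; the composition screen, not the tree, is the
reliable detector in that regime.

## In-silico PCR

Degenerate primers are matched under IUPAC set-intersection
semantics. A binding site requires at most 2 mismatches (default)
*and* an exact match at the 3 template bases facing the primer's 3′
end — the 3′-anchor rule, a standard proxy for annealing chemistry,
since polymerase extension is far more sensitive to 3′-terminal
mismatches. Reverse primers are searched as their reverse complement
on the plus strand. Every forward/reverse site combination up to a
3000-nt extension limit yields an amplicon; outcomes are classed the
way gel lanes are scored (expected band; expected plus aspecific;
aspecific only; no product), with the expected-size window at ±10% of
the configured product length. The built-in registry carries the
seven I3-M11 survey primers bit-exact to their published sequences
plus the universal Folmer pair. Melting-temperature thermodynamics
are out of scope; the matching rule is a structural approximation,
not a chemistry model.

## The synthetic-data generator

`make_dataset()` emulates the statistical structure of the survey the
analysis is designed for. Defaults:

| parameter | default | rationale |
|---|---|---|
| taxon design | 33 genera / 41 species / 102 specimens | the survey's screening design (8 genera carry 2 species; 20 species carry 3 specimens, 21 carry 2) |
| fragment | 393 nt (I3-M11-like), frame 0 | upper end of observed fragment lengths; `657` gives a Folmer-like fragment |
| base composition | A .27, C .12, G .19, T .42 | observed AT-rich COI composition |
| kappa | 4 | typical mitochondrial transition bias |
| codon rate multipliers | (1, 0.3, 8) | third position far fastest, second slowest; reproduces the per-position distance ordering |
| intraspecific divergence | 0.005–0.03 expected K2P | bulk of observed intraspecific distances |
| congeneric divergence | 0.10–0.26 | observed congeneric minima |
| intergeneric floor | 0.12 (genus depths drawn up to 0.50) | observed intergeneric minimum |
| numt rate | 10%, evolving at 0.3× | numts are common and evolve at the slower nuclear rate, making them sequence-similar to true copies — the hard case |
| contaminants | 5%, GC-shifted (A .22, C .28, G .27, T .23) | bacterial-like composition |

Sequences evolve under the exact K2P site-transition probabilities at
the target branch length, scaled per codon position; divergence is
parameterized directly as expected K2P distance so generator targets
and analysis estimates share units, making recovery tests direct
(realized distance at a 0.02 target is unbiased to within 0.005).
Substitutions creating a frame-0 stop codon are reverted, keeping
lineages coding. Numts are copies of a specimen's sequence evolved at
0.3× rate and given either 1–2 internal stop codons or a 1–2 nt
deletion (a frameshift); contaminants are independent GC-shifted
coding sequences. The taxonomy is a star phylogeny at each level
(genus depths half a uniform draw in [0.12, 0.50], species depths
half of [0.10, 0.26], specimen depths half of [0.005, 0.03]), so
expected pairwise divergences land in the configured ranges.

**What the generator does not emulate** — and hence what passing
tests do not establish about real data: alignment error (sequences
are generated aligned; real pipelines depend on an aligner),
population structure within species (star genealogies, no
coalescent), indel evolution in genuine sequences (indels are
injected only into numts, so the indel-warning path sees no clean
carriers by default), composition stationarity (the K2P process
drifts toward uniform composition along deep branches, so simulated
datasets are less AT-rich than their root), primer-site variability
(in-silico templates embed exact binding sites; real amplification
failure from primer mismatch is not simulated), and chromatogram
quality (sequencing success enters as a user-supplied boolean).
Consequently the amino-acid variability of deep simulated datasets
exceeds what purifying selection would allow in real COI — the
generator has no selection beyond stop-codon rejection.

## Numerical choices

* Threshold grids are generated as exact decimals
  (`round(step * k, 10)`) because the gap fractions use strict
  inequalities; naive floating accumulation would misclassify
  boundary values.
* Histogram bins are half-open `[kw, (k+1)w)`; a distance exactly at
  a bin edge belongs to the upper bin; a pair exactly at the
  threshold belongs to neither gap fraction and is counted
  separately.
* Internal stops exclude the final codon: a terminal stop is ordinary
  for a fragment reaching the gene end.
* Coordinates are 0-based half-open internally (binding sites);
  user-facing reports (indel positions, alignment columns) are
  1-based inclusive, matching biological convention.
* `U` is accepted on input and folded to `T`; any other non-IUPAC
  character is a parse error naming the record and line (fail fast on
  corrupt data).
* The FASTA writer wraps at 60 columns, fixing a canonical dialect
  for round-trip testing.

## Problem sizes used by the test suite

The suite validates NJ on 200 random additive trees of 4–12 taxa and
25 generic matrices against an independent implementation; the
translation table on all 64 codons plus 1,000 random
frame-identifiable ORFs; the barcoding-gap recovery on 100 simulated
surveys at the default design; and QC sensitivity on 50 surveys
(criteria: every stop-bearing numt removed with reason `stop_codon`;
at least 90% of all injected artifacts removed). These sizes keep the
whole suite under a few minutes on one CPU while leaving the
statistical assertions comfortably powered.

## Known limitations

Beyond the generator caveats above: no bootstrap support or
model-based tree inference (NJ only, as in the survey design); no
ABGD/GMYC/PTP-style species delimitation (fixed and scanned
thresholds only); no gamma rate correction or model selection for
distances; the composition screen is a coarse contaminant detector
compared to a real similarity search; and trees involving filled
(saturated) distances should be read as QC devices, not phylogenies.
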