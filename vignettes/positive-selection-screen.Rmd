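---
title: "Screening for episodic positive selection with branch-site models and false-positive filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for episodic positive selection with branch-site models and false-positive filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posscreen)
```

## The problem

Comparative genomics detects adaptive protein evolution by contrasting the
nonsynonymous/synonymous rate ratio ω = dN/dS between lineages and sites:
ω > 1 on a branch, at a site, signals positive selection. The branch-site
test asks a focused question — did a *designated* lineage (the foreground)
experience episodic selection at a *few* sites — and is the workhorse of
genome-wide screens, for example screens contrasting groups of species
with different life-history strategies (here: seasonal versus non-seasonal
breeding mammals).

Two realities make the raw test unreliable at genome scale. First,
misalignment: a locally wrong multiple alignment manufactures spurious
nonsynonymous changes on whichever branch the errors fall, and the test
happily calls them selection. Second, sequence/assembly/annotation error
in draft genomes does the same. `posscreen` implements the full screen —
ortholog calling, branch-site inference, and two dedicated false-positive
filters (sum-of-pairs window scoring and cDNA validation) — together with
a simulator rich enough to test every stage without genome downloads.

## The model

Sequences evolve by a GY94 codon process on the 61 sense codons (stop
codons are excluded from the state space): single-nucleotide changes at
rate `pi_j * kappa^[transition] * omega^[nonsynonymous]`, zero for
multi-nucleotide changes. The modified branch-site Model A layers four
site classes on a tree with one foreground branch:

| class | proportion                  | background ω | foreground ω |
|-------|-----------------------------|--------------|--------------|
| 0     | p0                          | ω0 ∈ (0,1)   | ω0           |
| 1     | p1                          | 1            | 1            |
| 2a    | (1−p0−p1)·p0/(p0+p1)        | ω0           | ω2 ≥ 1       |
| 2b    | (1−p0−p1)·p1/(p0+p1)        | 1            | ω2 ≥ 1       |

The gene-level test compares the maximum likelihood of this model against
the null with ω2 fixed at 1, via `2(lnL_alt − lnL_null)` against χ²
with one degree of freedom; the comparison is conservative because the
null value lies on the boundary. Genes pass at p ≤ 0.01 **and**
Benjamini–Hochberg q < 0.05, the FDR family being all genes tested for
one foreground species. Sites within passing genes are localized by Bayes
Empirical Bayes: the posterior probability of classes 2a+2b, integrating
over a uniform prior on a discretized parameter grid (a triangular d×d
grid on (p0,p1) restricted to p0+p1 ≤ 1, and d = 10 midpoint grids on ω0
over (0,1) and ω2 over (1,11)), with κ, codon frequencies and branch
lengths held at their MLEs. Sites are reported at posterior > 0.95, in
original (pre-cleaning) alignment coordinates.

### Numerical choices

* **Gap handling.** Any codon column containing a gap or an `N` in any
  taxon is removed before inference (`strip_gap_columns()`), mirroring
  the usual clean-data behaviour of branch-site software; a column map
  translates retained indices back to input coordinates.
* **Likelihood.** Felsenstein pruning over site patterns with the class-
  specific transition matrices; the 61×61 generator is diagonalized via
  the symmetric similarity transform available for reversible processes,
  and the pruning inner loop is compiled (RcppArmadillo) with per-node
  rescaling for numerical safety.
* **Optimization.** The search runs in unconstrained space (log κ, logit
  ω0, log(ω2−1), log scale) with the class proportions (p0, p1) profiled
  out at every evaluation by EM — the four class weights factor into two
  independent Bernoulli parameters, so the inner problem is a cheap
  two-parameter mixture fit. The null is fitted first and seeds the
  alternative, which is restarted from a ladder of ω2 values (plus
  seeded jitter); ω2 is capped at 999 and ω0 bounded inside (0,1). If
  the alternative optimizer ends below the null, the fit falls back to
  the null solution with ω2 = 1 — a valid boundary point — so nesting
  (`lrt_stat ≥ 0`) holds exactly.
* **Branch lengths.** Input trees supply relative branch lengths; a
  single tree-scale multiplier is estimated under the null and held
  fixed for the alternative. Estimating all branch lengths per gene
  would multiply the optimization dimension roughly tenfold for no gain
  in the screen's decisions; the scale absorbs both overall rate and the
  rate-normalization convention.
* **Codon frequencies.** F3x4 (position-specific nucleotide frequencies,
  lightly smoothed) estimated from the cleaned alignment by default;
  `"equal"` is available and is what the exact-likelihood oracle tests
  use.

## The two false-positive filters

**SP penalty scoring.** For each candidate site, walk outward from the
site column until 15 focal-sequence residues are collected upstream and
downstream (gap columns of other taxa stay inside the window — otherwise
gap penalties could never fire; the site column itself is excluded as the
hypothesis under test). With `n` the focal residues actually available in
a stream (sites near a gene edge have fewer), the stream's base penalty is
S = 15/n. Column scoring: identical residues 0, mismatch −S, residue
against gap −2S, gap against gap 0 (shared gaps carry no pairwise
evidence). The *general* score sums both streams over all unordered
sequence pairs and divides by the number of sequences N; the *individual*
score sums the focal-versus-other pairs, unaveraged. A site survives iff
general > −50 and individual > −15, both strict. The reading of "sum of
the penalty scores from each of the two compared species" as
sum-over-all-pairs/N is one of two defensible readings of the published
rule; it is the package default and the individual score is left
unaveraged, matching the rule's separate wording.

**cDNA validation.** Independently sequenced transcript fragments are
mapped to the gene's CDS by local nucleotide alignment (match +2,
mismatch −3, gap open 5 / extend 2, both orientations; mappings under a
score/length floor are rejected). A fragment *covers* a site when its
mapped interval contains all three codon positions; the site is *valid*
iff at least one covering fragment matches the codon exactly and
ungapped, *invalid* if covered but never matched, *unmapped* otherwise
(unmapped sites are excluded from false-positive statistics and reported
separately). Adding fragments can therefore only improve a verdict.

## The synthetic data generator

The generator defines the conditions every stage is tested under:

* codon alignments evolved along a user tree under the exact Model A
  process (classes drawn i.i.d.; the foreground branch switches classes
  2a/2b to ω2), with branch lengths in expected substitutions per codon
  under the background mixture;
* three named misalignment operators — `gap_burst`, `shuffle`, `shift` —
  each a parameterized window on one taxon, plus per-nucleotide
  substitution error and a frameshift operator, each mapping to one
  failure class of real pipelines (misalignment, sequencing error,
  annotation error), with a truth table of every touched column;
* cDNA fragments as coordinate-tracked substrings of a taxon's CDS,
  optionally carrying injected errors; and proteome sets with known 1:1
  orthology and optional diverged paralog decoys.

All randomness flows from one integer seed through a splittable-stream
contract (`derive_seed()`), so every fixture is reproducible to the byte.

What the generator does *not* emulate: indel evolution (gaps enter only
through the corruption operators), alignment-program behaviour, rate
variation beyond Model A's classes, and empirical codon bias of real
genomes. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model's own assumptions, not
robustness to every pathology of real genome data.

## Study conditions used in tests and reported runs

Two reference trees mirror the two species-set designs of such screens: a
"distant" six-taxon tree (total length ≈ 1.3 substitutions/codon, e.g.
rodent outgroups) and a "close" six-taxon primate-like tree with
literature-scale codon branch lengths (human/chimp 0.008, macaque 0.04,
marmoset 0.055). Defaults: κ = 2, ω0 = 0.1, p0 = 0.7, p1 = 0.2, equal
codon frequencies in the simulator.

The SP-filter discrimination checks run on the close tree: the −50/−15
thresholds presuppose that the flanks of a genuine site are largely
conserved, which holds at primate divergence; at distant-set divergence
even true sites frequently fail the individual threshold — the same
behaviour visible in the published per-species retention rates. Test
calibration uses 200 null genes of 300 codons on the distant tree
(type-I error at p ≤ 0.01 stays below 0.05; the boundary null makes the
test conservative); parameter recovery uses 20 replicates of 1500 codons
at ω2 = 4, where the median recovered ω2 must land within a factor of
two and BEB-flagged sites must be enriched for true class-2 sites. The
analysis drivers under `analysis/` run a smaller six-species, eight-gene
screen (450 codons, intermediate divergence) end to end; these sizes keep each stage in the
minutes range on one CPU and are stated here as the package's chosen
desk-scale study conditions.

## Design choices on genuinely open points

* The FDR family is per foreground species (matching per-species count
  reporting), not global across species.
* Background species for a foreground test are the *opposite* breeding
  group, following the worked example of the published design ("the
  human branch ... foreground ... the other five species in the seasonal
  breeding group ... background").
* Fold changes between group means are always emitted at full computed
  precision; rounded displays round half up to two decimals.
* The RBH search replaces an external BLAST with an internal affine-gap
  local alignment (BLOSUM62, open 11 / extend 1); the E-value cutoff of
  a search engine has no exact analogue here and becomes a minimum-score
  floor (default 40) — an acknowledged stand-in, stated in the
  configuration, not an equivalence.
* Corruption parameters (window widths, error rates) are fixtures: no
  quantitative error model for real assemblies is claimed.

## Known limitations

The likelihood engine implements exactly one model (branch-site Model A
and its null); there is no M0/M7/M8, no tree search, and trees without
branch lengths are rejected rather than estimated (an NJ fallback from
nucleotide distances exists for topology only). BEB integrates over the
standard grid with other parameters fixed at MLEs, so its posteriors
inherit MLE uncertainty. The screen's runtime is dominated by per-gene
optimization; at genome scale the per-gene fits parallelize trivially,
but the package itself runs single-threaded.
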