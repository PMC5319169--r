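---
title: "Methods: comparative annotation and molecular evolution of divergent plant mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative annotation and molecular evolution of divergent plant mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plant mitochondrial genomes usually evolve slowly, but a handful of
lineages — the mistletoe genus *Viscum* chief among them — show
synonymous substitution rates elevated by an order of magnitude or
more. At that level of divergence, default-parameter BLAST searches
miss genuine homologs, and a genome can look as if it had lost most of
its respiratory genes when in fact it retains them in highly diverged
but functional form. `mitorescue` implements the full analysis needed
to settle such a question: sensitive homology search and annotation,
intact/pseudogene classification, codon-model selection analysis,
compensatory-change analysis of rRNA secondary structures, and a
phylogenetic screen for horizontally transferred genes — together with
a seeded synthetic-mitogenome generator, so that every stage can be
validated against known ground truth without any external data.

# Homology search and annotation

## Seeded search with an exact oracle

`seeded_local_search()` is a BLAST-style seed-and-extend search: every
maximal exact word match seeds an ungapped X-drop extension, and
extensions above a trigger score enter a gapped stage, implemented as
an optimal local DP in a window around the ungapped HSP that is
re-expanded whenever the optimum touches the window boundary. A gap of
length $k$ costs `gap_open` $+\,k\,\cdot$ `gap_extend`, the convention
of BLASTN, so published parameter settings carry over directly. Two
schemes are provided:

* `sensitive_scheme()` — word size 7, reward 5, penalty −4, gap open
  8, gap extend 6, 20% identity floor. These settings recover homologs
  at 40%+ nucleotide divergence.
* `default_scheme()` — word size 11, reward 2, penalty −3, gap open 5,
  gap extend 2, for queries from a close relative.

Filtering is by raw score (default ≥ 50 for the sensitive scheme)
rather than E-values: Karlin–Altschul calibration for gapped scores
adds nothing at desk scale and raw thresholds are exactly
reproducible. The gapped-stage trigger (ungapped score 60 for the
sensitive scheme) is a speed heuristic; a homology whose every
ungapped segment scores below the trigger would be missed, which at
these parameter values requires more than ~75% divergence — beyond the
search's design range. `smith_waterman()` is the exact full-matrix
oracle; by construction the seeded search can never report a better
score, and the test suite checks that on planted homologies it almost
always reports the same one.

## Chaining and gene models

`chain_hsps()` assembles colinear HSPs (same query, same strand,
consistent query and subject order) into the highest-scoring chain by
dynamic programming, penalizing genomic gaps at 0.2 per nucleotide and
query overlaps at 2 per nucleotide, and breaking score ties by
leftmost genomic start. Genomic gaps under 30 nt are treated as coding
indels and merged into one exon; larger gaps become introns. The gap
penalty matters: with ~350 random score-50 HSPs per divergent query
against a 40 kb genome, nearly free chaining would assemble spurious
"genes" from noise, while 0.2/nt leaves true introns (a few hundred
nt) cheap relative to real exon scores.

## Intactness classification

`classify_gene_status()` stitches the chain's HSP alignments into one
query-anchored alignment, padding unaligned query stretches between
exons with `N` (which can never spell a stop codon), and reads the
subject codon-by-codon in the reference frame:

* **Frameshifts.** Gap runs are grouped when separated by fewer than
  30 aligned columns; a group is a frameshift only when its *net*
  indel length is not a multiple of 3. This distinction is essential:
  at 30–40% divergence the aligner occasionally introduces
  compensating gap pairs whose net is zero — treating each gap as a
  frameshift would misclassify a substantial fraction of genuinely
  intact genes.
* **Premature stops.** A subject stop codon aligned to a non-terminal
  reference codon, skipping codons listed in the RNA-editing table and
  codons inside locally frame-shifted windows (whose subject triplet
  is not in the reference frame).
* **Length.** Disruption-free models are `intact` at aligned fraction
  ≥ 0.80, `truncated_intact` in [0.60, 0.80) — the regime of a gene
  like *sdh3*, short relative to its reference but conserved and
  plausibly functional — and `pseudogene` below. The thresholds are
  configurable because no universal criterion exists; the three-way
  call avoids the known failure mode of a pure length cut-off.
* **Start/stop leniency.** A missing ATG or terminal stop never
  triggers a pseudogene call: plant mitochondrial transcripts can gain
  both by C-to-U editing.

A gene is `absent` when no chain reaches score 150 *and* 30% coverage.
Both floors are deliberately above the per-HSP reporting threshold:
with reward 5, a raw score of 50 corresponds to a 10 nt exact match,
which arises by chance hundreds of times per genome.

`orf_persistence_probability()` quantifies the argument that long
stop-free ORFs in a hypermutating genome are maintained by selection:
it computes the probability that $n$ random substitutions leave an ORF
stop-free, treating each codon as a Markov chain over the 64 codon
states with a binomial number of hits, exact within codons and
independent across codons (a Monte-Carlo mode cross-checks the
approximation).

# Codon-model analyses

## Models

All likelihood work uses the Goldman–Yang codon model in its
"simplified" form: single-nucleotide instantaneous changes only, one
transition/transversion ratio $\kappa$, target-codon frequencies
$\pi_j$, and a nonsynonymous factor $\omega$ — no site-rate variation
inside the codon model. Frequencies default to F3x4 estimated from the
data (uniform optional); the rate matrix is normalized to one expected
substitution per codon per unit time, and $d_N$ and $d_S$ follow from
the standard flux decomposition: with $\rho_S$ the synonymous share of
substitution flux and $S$ synonymous sites per codon (3 × the neutral
flux share), $d_S = t\,\rho_S / S$ and likewise for $d_N$.

`ng86_dnds()` is the counting companion: Nei–Gojobori site counting
with stop-codon mutations disregarded, equal-path averaging over
stop-free mutational routes for multi-difference codons, and
Jukes–Cantor correction. When the correction is undefined (proportion
≥ 3/4) on one side only, that rate is reported as `NA` with a
saturation flag rather than refusing the comparison — extreme
synonymous divergence is exactly the regime of interest here. (The
companion rule, erroring only when *both* sides saturate, follows from
the same policy.)

Optimization is bounded quasi-Newton on log-transformed parameters
(convergence 1e-8 to 1e-10 on the objective). The pairwise fit
defaults to one jittered restart from the incumbent optimum; a
three-parameter unimodal-in-practice surface does not benefit from
wide random restarts, and the moment-based starting point (codon
p-distance) makes convergence fast and reproducible.

## The relaxation test

`relaxation_test()` implements the branch-model selection-intensity
test: reference branches share $K$ discrete $\omega$ categories
(values and proportions estimated; $K = 3$ by default), test branches
use $\omega_i^k$, the null fixes $k = 1$, and the LRT is referred to
$\chi^2_1$. $k < 1$ with a significant LRT is relaxation. Two
simplifications keep it at desk scale, both deliberate: proportions
are shared between branch sets with no random-effects averaging over
models, and branch lengths (up to one jointly estimated scale factor)
plus $\kappa$ come from a single-$\omega$ first stage and are then
held fixed. The test suite verifies the operating characteristics this
design actually delivers: empirical type-I error within [0.02, 0.09]
at $\alpha = 0.05$ over 200 null replicates, power ≥ 0.8 and median
$\hat{k}$ near truth at $k = 0.3$ with 500 codons, and approximate
reciprocity of $\hat{k}$ when test and reference sets are swapped on a
mirror-symmetric tree. If two $\omega$ categories collapse during
fitting, the test refits with $K-1$ and sets a `collapsed` flag.

# rRNA structure analysis

`map_structure()` carries a reference secondary structure (dot-bracket
input; `()[]{}` alphabets, crossing or square/brace pairs flagged as
pseudoknots) through a pairwise alignment onto a query sequence, and
`classify_paired_changes()` partitions every mapped pair into
unchanged, fully compensatory (both partners changed, pairing
retained), half (one partner changed, pairing retained — the GU wobble
route), disruptive (pairing lost) or pair-deleted. GU/UG counts as
pairing-retained, the standard wobble treatment for rRNA helices.
Internally everything is DNA-alphabet (`U` mapped to `T` on input).
`conserved_core_identity()` applies the gap-excluded identity rule
separately inside and outside a conserved-core mask. The module takes
the alignment as input (from `align_rrna()`, a Needleman–Wunsch
wrapper, or computed externally); it does not attempt structure-aware
alignment, because the analysis is superposition onto a *fixed*
reference structure.

# Phylogenetics and the HGT screen

`gtr_gamma_lnL()` is a pruning-algorithm likelihood engine over 4
nucleotide states with discrete-gamma rate variation (4 categories,
mean-of-quantile discretization). `optimize_branch_lengths()` fits
branch lengths (optionally the gamma shape and exchangeabilities)
either jointly by quasi-Newton (default; fast) or by coordinate-wise
Brent sweeps, which guarantee a monotone likelihood trace.
`search_ml_tree()` is exhaustive below 6 taxa and NNI hill-climbing
from random-addition starts above, capped at 12 taxa; constraints are
clade (bipartition) sets and incompatible moves are rejected.

`rell_topology_tests()` resamples per-site log-likelihoods (RELL — no
re-estimation). KH uses the normal approximation on the centred
resampled difference to the best topology; SH applies the
max-correction over topologies; AU fits the signed-distance/curvature
pair $(d, c)$ of the multiscale model
$\mathrm{bp}(r) = \Phi(-(d\sqrt{r} + c/\sqrt{r}))$ (scales 0.5–1.4)
to the per-scale win *counts* by binomial maximum likelihood,
initialized from weighted least squares on the informative scales, and
reports $1 - \Phi(d - c)$, normal theory only. The count likelihood is
the important choice: when a topology is strongly rejected, most
scales record zero bootstrap wins, and a least-squares fit on the
clamped normal quantiles becomes ill-conditioned and can inflate the
p-value by an order of magnitude, whereas zero counts remain fully
informative in the binomial fit (which reduces to the usual
least-squares solution when counts are moderate). Ties in the
per-replicate winner are broken uniformly at random so that identical
log-likelihood vectors yield bootstrap proportions near 0.5 rather
than a degenerate 0/1 split. `B` defaults to 10,000; below 1,000 a
warning flag is set.

`flag_hgt_candidates()` formalizes the two-pronged transfer argument:
a gene is an `hgt_candidate` only when (i) its divergence statistic is
anomalous on the low-divergence side — the leave-one-out z-score of
the focal-vs-reference percent identity is at or above 2.5 (the
threshold is this package's own choice; leave-one-out keeps a single
strong outlier from inflating its own reference scale) — **and** (ii)
the vertical-constraint topology, derived as the smallest species-tree
clade containing the focal taxon and at least one other sampled taxon,
is rejected by the AU test at $\alpha = 0.05$. Genes failing (i) are
`vertical` without any tree search, which keeps the genome-wide screen
cheap; genes passing (i) but not (ii) are `inconclusive`.

# The synthetic-data generator

`simulate_gene_family()` evolves codon sequences by an exact
continuous-time Gillespie jump process per site per branch, under GY94
with branch-specific rate multipliers and $\omega$. The jump
formulation — rather than sampling from matrix-exponential transition
probabilities — makes realized synonymous and nonsynonymous
substitution counts, and the complete event log, part of the ground
truth; `replay_sim()` verifies that replaying the log reproduces every
leaf exactly. Codon frequencies default to uniform over the 61 sense
codons and $\kappa$ defaults to 2.0 — conventions, since the
mutational spectrum of such lineages is not characterized well enough
to fix either from data.

The default scenario (`viscum_scenario()`) encodes the study regime:
six taxa; the focal + sister clade carries a 20× rate multiplier with
per-gene $\omega$ drawn uniformly in [0.2, 0.85] on its three branches
(background 0.1), placing most divergence on the clade's ancestral
branch; 19 intact genes with realistic mitochondrial lengths, one of
them a recent transfer simulated on a donor-grafted topology (focal
attached beside the donor with short branches, no rate elevation —
hence its anomalously *low* divergence); nine nad-like pseudogenes
(one nonsense plus one frameshift each); two genes absent from the
focal genome but present in the panel; an RNA-editing table covering
~2% of intact-gene codons, including one edited genomic stop; and two
rRNAs (240 and 360 nt, helix-based random structures) evolved with 80%
of paired-position changes compensatory. `assemble_mitogenome()`
embeds the genes in Gaussian-length spacers (mean 400 nt) on random
strands, splits three genes into two exons, and marks the record
circular; features may wrap the origin.

What the generator does *not* emulate — and hence what passing tests
cannot certify about real data: within-gene indel evolution outside
explicit pseudogenization events, repeat-mediated recombination and
sublimon dynamics, base-composition heterogeneity along the genome,
chimeric gene conversion, and real RNA-editing biology (the editing
table is consumed, not predicted). Closed-loop results on this
scenario demonstrate internal correctness of the pipeline, not field
performance on arbitrary assemblies.

# Problem sizes and numerical choices

The validation suite runs at sizes chosen to make Monte-Carlo
assertions sharp but cheap: 100 replicates × 500 codons for pairwise
recovery, 200 null replicates × 300 codons and 30 power replicates ×
500 codons for the relaxation test, 500 planted homologies for the
search oracle, 50 replicates × 5 kb for the AU behaviour, and 50
scenario seeds for the closed loop. Likelihood tolerances: pruning vs
brute-force enumeration at 1e-10; permutation invariance at 1e-8;
optimizer convergence 1e-8 to 1e-10 on the objective. Branch lengths
are bounded in [1e-7, 20] substitutions per site (codon models: per
codon), $\kappa$ in [0.05, 100], $\omega$ in [1e-5, 50]. Degenerate
inputs fail fast: empty FASTA records, non-ACGTN characters, unbalanced
brackets, editing indices beyond the gene, unassigned branch classes,
and saturated distances all raise informative errors.

# Known limitations

* The annotation classifier reads frames through the chained HSP
  alignment; genes whose true exon boundaries fall inside regions the
  search cannot align (beyond ~75% divergence) will lose coverage and
  may be down-called to `truncated_intact`.
* The relaxation test's fixed-branch-length two-stage design trades a
  small amount of power for large speed gains; its calibration is
  verified under the generator's regime, not proven in general.
* The AU implementation is the normal-theory multiscale fit; it does
  not enumerate edge sets as the reference implementation can, so
  p-values in pathological near-degenerate cases may differ.
* The tree search is deliberately capped at 12 taxa.
* Percent-identity statistics exclude gap columns everywhere; analyses
  that should weight indels will need their own statistic.
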