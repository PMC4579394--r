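---
title: "Haplotype-copying imputation, panel merging and evaluation with hapimpute"
author: "hapimpute authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-copying imputation, panel merging and evaluation with hapimpute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapimpute)
```

## Scope

`hapimpute` implements genotype imputation from phased haplotype reference
panels with a Li–Stephens copying hidden Markov model, two heuristics for
selecting the reference haplotypes that condition the HMM, a
reciprocal-imputation procedure for merging two phased panels into a single
panel over the union of their variants, and the standard accuracy metrics
(info score, true r², MAF stratification) with leave-one-out and
pseudo-GWAS evaluation harnesses.  A seeded simulator generates all inputs
needed for end-to-end experiments, so nothing in the package depends on
managed-access data.

## The copying model

A pre-phased study haplotype observed at $T$ typed sites is modelled as an
imperfect mosaic of $K$ reference haplotypes.  The hidden state at typed
site $t$ is the reference haplotype being copied.  Over a gap of $d$ cM
between consecutive typed sites the copying template is kept with
probability $\exp(-\rho/K)$ where $\rho = 4 N_e d / 100$; otherwise it
switches to a uniformly drawn template (including, possibly, the current
one).  The emitted study allele equals the copied reference allele with
probability $1-\varepsilon$.  The copying-error rate is derived from the
Watterson mutation parameter for the conditioning set,

$$\theta = \Big(\sum_{i=1}^{K-1} 1/i\Big)^{-1}, \qquad
  \varepsilon = \frac{\theta}{2(\theta + K)},$$

and may be overridden through `hmm_params(epsilon = )`.  Two deliberate
choices here:

* $\varepsilon$ is recomputed from the **selected** $K$ (after haplotype
  selection), not from the full panel size — the HMM in use has $K$ states,
  and its mutation model should refer to that conditioning set.
* `hmm_params()` accepts $\varepsilon$ up to and including $0.5$; the
  boundary value makes emissions uninformative and is useful only for
  degenerate symmetry checks.

`forward_backward()` computes exact posterior copying probabilities with
per-site normalisation of the forward and backward messages; the posterior
is invariant to the scaling scheme, and the test suite pins it against
exhaustive enumeration over all $K^T$ copying paths on small instances.

### Untyped sites

Imputation targets every site of the reference legend.  At a typed site the
posterior state distribution is mixed with the reference alleles through
the emission model, $P(\mathrm{ALT}) = \sum_k \gamma_{tk}\,
[(1-\varepsilon) a_k + \varepsilon (1-a_k)]$.  At an untyped site the state
distribution is interpolated **linearly on cumulative genetic distance**
between the flanking typed sites; before the first (after the last) typed
site the nearest posterior row is used unchanged.  Linear-in-cM
interpolation is the simplest scheme consistent with a recombination
process that is uniform in genetic distance; it is a documented choice of
this package, not a claim about what any particular existing tool does
internally.  If two flanking typed sites sit at identical map positions the
interpolation weight falls back to $1/2$.

Sites monomorphic in the **full** reference panel bypass the HMM and take
the panel allele frequency (exactly 0 or 1).  Sites monomorphic merely
within the selected subset still go through the emission mixture, so a
unanimous ALT among selected references yields $1-\varepsilon$, not $1$.

Diploid calls multiply the two independent haploid posteriors
($p_2 = ab$, $p_0 = (1-a)(1-b)$, $p_1$ the remainder; dosage $a+b$), which
is exactly the pre-phasing assumption: phase is taken as known and the two
haplotypes are imputed independently.  Best-guess haplotype alleles
threshold the posterior at $0.5$, with the tie resolved to the reference
allele.

## Choosing the conditioning haplotypes

Three strategies, all deterministic (ties always resolve to the lower
reference index) and all computed per study haplotype on the typed sites of
the (buffered) chunk:

* **all** — no approximation.
* **hamming** — the classical region-wide approximation: keep the $k$
  references with the smallest Hamming distance to the study haplotype
  across all typed sites of the chunk.  Defaults follow chromosome-scale
  practice ($k = 10{,}000$, clipped to the panel size, so the default is
  exact on small panels).
* **tracts** — a local-sharing rule: place a small number of evenly spaced
  anchor sites over the chunk's typed sites (default 16); at each anchor
  rank references by the length of the maximal run of consecutively
  matching typed sites through that anchor (`shared_tract_length()`), take
  the top $\lceil k/\mathrm{anchors}\rceil$ per anchor, and union the sets.
  An over-full union keeps the references with the largest
  maximum-over-anchors tract; a short union is topped up with the best
  remaining region-wide Hamming candidates.

The tract rule is this package's concrete instantiation of the local-
sharing idea: scoring in typed-site counts rather than cM, and a uniform
per-anchor quota, were chosen for determinism and an
$O(\mathrm{anchors}\cdot K\cdot T)$ cost; both are exposed as parameters.
The rationale for local sharing is that a reference carrying a rare allele
on a long shared segment around one locus can be globally distant from the
study haplotype, so a region-wide distance discards exactly the references
that rare-variant imputation needs.  The package's acceptance experiments
measure the resulting ordering (full panel ≥ tracts ≥ hamming at MAF < 5%)
rather than asserting equivalence with any external implementation.

## Merging two phased panels

`harmonize()` applies the pre-merge filters and accounts for every
excluded site exactly once per panel: positions with duplicate records are
treated as multi-allelic and dropped; same-position sites with exchanged
REF/ALT are resolved by flipping one panel's allele codes (counted, not
dropped); same-position sites with genuinely different allele pairs are
dropped from both panels; and sites private to one panel whose minor-allele
count there is exactly 1 — cross-panel singletons — are dropped.  For
shared sites the combined allele count governs, so a variant that is a
singleton in each of the two panels separately but present in both is
retained.  `sites_after_filtering()` and `union_count()` expose the
resulting integer accounting as plain worked-example arithmetic, and the
merge report's inclusion–exclusion identities are re-checked on every run.

`merge_panels()` then performs the reciprocal imputation: every haplotype
of panel A is treated as a pre-phased haploid study sequence typed at the
shared sites and imputed against panel B at B's private sites (and vice
versa), the posteriors are collapsed to best-guess alleles, and the
haplotypes are stacked over the position-sorted union legend.  Haploid
imputation is the only mode consistent with treating the panel haplotypes
as known.  Observed alleles are never altered — the merge output restricted
to either input panel's sites and rows is bit-identical to that input — and
the operation can run per buffered chunk (`chunk_bp`, `buffer_bp`) exactly
like study imputation.

## Accuracy metrics and harnesses

* **info** (expected r²): with per-sample genotype probabilities and
  $e_i = p_{1i} + 2p_{2i}$, $f_i = p_{1i} + 4p_{2i}$,
  $\hat\theta = \sum_i e_i/2N$,
  $$\mathrm{info} = 1 - \frac{\sum_i (f_i - e_i^2)}
    {2N\,\hat\theta(1-\hat\theta)},$$
  defined as 1 when $\hat\theta \in \{0,1\}$ and clamped to $[0,1]$.  It is
  a panel-free confidence metric: no truth genotypes are needed.
* **true r²**: squared Pearson correlation between imputed dosages and
  held-out truth genotypes; undefined when either vector is constant.
  Undefined sites are counted and reported but excluded from bin means —
  silently scoring them 0 would bias the means, and scoring them 1 would
  hide total failures.
* **MAF bins**: default edges $\{0.1\%, 0.5\%, 1\%, 2\%, 5\%, 50\%\}$,
  covering the thresholds at which rare/low-frequency behaviour is usually
  quoted; info-count tables use info edges $\{0.4, 0.8, 1\}$.  Accuracy
  curves bin by truth-genotype MAF; count tables can bin by imputed MAF
  (`maf_source = "imputed"`), matching the different axis semantics of the
  two displays.

`leave_one_out_eval()` removes each diploid sample from the panel in turn,
exposes its typed sites, imputes the rest and scores against the held-out
genotypes (optionally on a seeded subsample of samples).
`pseudo_gwas_eval()` reduces a truth panel to its typed sites and imputes
from an independent reference panel.  `compare_configs()` runs several
(panel, selection) configurations against identical inputs.

## The simulator

`sim_config()`/`make_scenario()` generate: a founder haplotype pool with
site frequencies drawn from a neutral-like $1/f$ spectrum truncated to
$[1/(2n_\mathrm{founders}), 0.5]$; reference and study haplotypes as
copying mosaics of the founders (template switches with probability
$1-\exp(-\mathrm{switch\_rate}\cdot d_\mathrm{cM})$, per-allele flips with
probability `mut_rate`); panel-private site sets carved disjointly from the
segregating sites; planted private singletons so that the cross-panel
singleton filter has work to do; and an array-like typed mask that prefers
shared sites with MAF ≥ 5%.  The genetic map is uniform at 1 cM/Mb unless
overridden — no simulation map is implied by anything else in the design,
and uniform is the neutral choice.

Default scenario sizes were fixed once for all experiments: 5,000 sites
over 5 Mb, 400 + 200 reference haplotypes, 100 study haplotypes (50
samples), 80 founders, switch rate 1 per cM, mutation rate $2\times10^{-4}$
per site per haplotype, 12% of sites typed.  These give several independent
LD segments per haplotype across the region — the structure both selection
heuristics feed on — while keeping a full three-strategy comparison around
a few seconds per seed.  The panel-size experiment uses 1,500 sites over
1.5 Mb with 120 study haplotypes and reference sizes {50, 200, 800}; 120
study haplotypes is the smallest even size whose truth-MAF grid can fall
strictly below 1%.

What the mosaic model reproduces: realistic allele-frequency decay,
block-wise LD, haplotype sharing between panels and study, panel-private
and rare variation.  What it does not: demography and selection, gene
conversion, mutation-rate heterogeneity, phasing and genotyping error in
the study haplotypes, and genuinely multi-allelic or structural variation.
Passing tests therefore demonstrate correct and well-behaved machinery
under a matched model, not performance on real cohort data.

One consequence deserves emphasis.  On real data the info metric is
reported to exceed the true r² for low-frequency variants, and the
acceptance machinery computes this gap (`info_minus_r2_maf_lt5` in the
acceptance script output).  Under this simulator the gap typically comes
out slightly *negative*: the model is perfectly specified, so the
posteriors are calibrated and info estimates the large-sample dosage–truth
r², while the finite-sample true r² at rare sites is inflated by the
scale-invariance of the Pearson correlation — with only a handful of
carriers, a site whose carrier merely receives the top-ranked dosage scores
r² ≈ 1 even when the absolute posterior mass is small.  Real cohorts are
evaluated on an order of magnitude more samples and with study-side error
the model does not capture, which is what pushes the direction the other
way.  We kept the simulator honest rather than engineering the bias in.

## Chunking and numerical choices

Imputation and merging operate on half-open core intervals tiling the
region (default 3 Mb) with buffers (default ±250 kb) clipped to the region
bounds; selection and the HMM see the buffered interval's typed sites, and
only core results are kept.  Coordinates are 1-based for sites and
half-open `[start, end)` for intervals.  Genetic maps interpolate linearly
between points and extrapolate as constants (local rate 0) outside the
mapped range.  Forward–backward messages are renormalised at every site;
state posteriors are accurate to the exhaustive-path oracle at $10^{-10}$,
and all probability triples are conserved to $10^{-9}$.  Selection has no
randomness anywhere; every generator is a pure function of its seed.

## Known limitations

* Unphased study genotypes (a diploid-pair HMM) and genotype-likelihood
  input are out of scope; inputs must be pre-phased.
* Only biallelic SNPs and INDELs are carried; multi-allelic records are
  rejected or dropped-and-counted at I/O.
* Merging is pairwise; merge three panels by iterating.
* The tract-selection quota and anchor placement are sensible defaults,
  not tuned optima; both are parameters.
* Chromosome X ploidy handling is not implemented.
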