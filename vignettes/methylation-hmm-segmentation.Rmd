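---
title: "Segmenting sparse CpG methylomes with a distance-aware binomial HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting sparse CpG methylomes with a distance-aware binomial HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(methylseg)
```

## The problem

Single-cell bisulfite sequencing of vertebrate oocytes (and other sparse
methylome assays) yields, per CpG dinucleotide, a handful of methylated and
unmethylated calls — typically 0–8 reads per site. Two features of such data
defeat an off-the-shelf HMM segmentation:

* **Unequal spacing.** CpGs are irregularly spaced, and the correlation of
  methylation state between neighbours decays with genomic distance. A chain
  with a fixed transition matrix treats a 10-bp neighbour and a 10-kb
  neighbour identically.
* **Unequal coverage.** A site seen by six reads carries far more
  information than a site seen by one, and sites with no coverage still
  matter for the spacing of their neighbours.

`methylseg` implements a K-state hidden Markov model addressing both, plus
everything needed to exercise it end to end: Bismark-format I/O with
single-cell QC, segment and locus callers, enrichment tests, descriptive
statistics, and a synthetic-data generator that is the exact sampling
counterpart of the model.

## The model

Each latent state (a *methylation regime*) $k$ has a mean methylation level
$\beta_k \in (0,1)$. A CpG site $t$ with read depth $n_t$ and methylated
count $m_t$ is emitted as

$$m_t \mid S_t = k \;\sim\; \mathrm{Binomial}(n_t, \beta_k),$$

so an uncovered site ($n_t = 0$) has emission probability 1 in every state:
it is carried along neutrally. The transition probability across a gap of
$d$ bp decays towards independence with correlation length $d_0$:

$$P(\text{stay}) = \frac1K + \frac{K-1}{K}\,e^{-d/d_0}, \qquad
  P(\text{switch to a given other state}) = \frac1K\left(1 - e^{-d/d_0}\right).$$

At $d = 0$ this is the identity; as $d \to \infty$ every row tends to the
uniform $1/K$. At $K = 4$ it coincides with the classical coefficients
$\tfrac14 + \tfrac34 e^{-d/d_0}$ and $\tfrac14 - \tfrac14 e^{-d/d_0}$; those
printed coefficients are row-stochastic *only* at $K = 4$, so for general
$K$ we use the normalized form above (a `literal_eq1` flag renormalizes the
four-state coefficients instead, for comparison).

### Depth-weighted training

During Baum–Welch training the per-site emission log-likelihood is
multiplied by $n_t + 2$, so deep sites dominate learning while uncovered
sites (weight 2 on a constant-1 emission) are inert. The M-step maximizes
this weighted objective, giving
$\hat\beta_k = \sum_t \gamma_{tk} w_t m_t \big/ \sum_t \gamma_{tk} w_t n_t$
with $w_t = n_t + 2$; this is a proper EM, so the weighted log-likelihood is
monotone non-decreasing (a property the test suite asserts). Transition
probabilities are *not* re-estimated: they are fixed by $d_0$, which is
treated as a tuned hyperparameter (see model selection below).

Because a CpG's state is coupled to both its left and right neighbour, the
reversed copy of every chromosome series is added to the training set, and
decoding is run in both directions.

**Accuracy of the weighted estimator.** The $(n_t+2)$ power tempers
(sharpens) the emissions, and the resulting estimator is slightly biased
outward at the extreme regimes. On the package's default synthetic
conditions (regimes 0.05/0.50/0.85, depth $\sim$ Poisson(3) truncated at 8,
~50,000 CpGs) the fitted means settle around 0.03/0.48/0.90: about $-0.02$
at the bottom regime and $+0.05$ at the top one, while an unweighted EM on
the same data recovers the truth to $\pm 0.001$. This is a property of the
weighted objective, not of the optimizer — initializing EM at the true
values converges to the same biased optimum. Users who need calibrated
$\beta$ estimates should re-estimate regime means from the decoded
segments; the regime *boundaries* (the segmentation itself) are what the
weighting is designed to sharpen. On small inputs (roughly $10^4$ covered
sites or fewer) the tempered objective can even prefer a degenerate optimum
with the bottom regime pinned at 0; at the default problem size we have not
observed this.

### Decoding and the unknown label

Decoding uses plain (unweighted) binomial emissions and the Viterbi
algorithm, run on each series forward and reversed. Sites where the two
directions agree receive that state; discordant sites are labelled unknown
(`NA`) and belong to no segment. With a symmetric transition kernel and a
uniform initial distribution the path posterior is exactly
direction-symmetric, so unknowns arise from the boundary asymmetry of a
non-uniform fitted initial distribution (and from ties); they are rare and
concentrate near regime boundaries. Posterior (forward–backward) decoding
is available through `predict(fit, x, type = "posterior")`.

### Model selection

`select_methyl_hmm()` fits every combination of a state-count grid and a
$d_0$ grid and ranks them by information criteria computed from the plain
forward log-likelihood — the training weights are a learning device and
would distort the parameter/observation balance if kept in the criterion:

$$\mathrm{AIC} = 2p - 2\ln L, \qquad \mathrm{BIC} = p\ln N - 2\ln L,
  \qquad p = \underbrace{K}_{\beta} + \underbrace{K-1}_{\pi} +
  \underbrace{1}_{d_0},$$

with $N$ the number of covered CpGs. Reversed training copies are excluded
from $\ln L$ (they duplicate the data). On three-regime synthetic data at
the default scale, BIC over $K \in \{2,3,4,5\}$ selects $K = 3$; with a
single simulated regime it selects the smallest $K$ in the grid.

For tuning on real genomes, `make_train_test_loci()` draws fixed-length
loci (default 54 loci of 300 kb) balanced across chromosome size classes
(for chicken: macro, intermediate, micro; membership is configurable since
no standard list exists — the shipped default takes chr1–5, chr6–10, and
everything else) and splits them evenly into train and test sets.

## From states to biology

```{r example}
sim <- simulate_methylome(chrom_lengths = c(chrA = 2e5, chrB = 2e5),
                          seed = 11)
fit <- methyl_hmm(sim$table, K = 3, d0 = 1250)
fit
segs <- states_to_segments(decode_states(fit, sim$table), min_cpg = 3)
head(segs, 3)
```

* **Segments** are maximal runs of one decoded state. Unknown sites are
  skipped: they do not break a run when the flanking states agree, and they
  are counted in neither segment. A segment spans its first to last member
  CpG (not the midpoints to the neighbouring runs — conservative, and the
  natural basis for computing mean segment lengths). Runs supported by
  fewer than `min_cpg` covered CpGs (default 3, to suppress single-site
  noise) are dropped but retained in an attribute, so CpG counts always add
  up to the series length.
* **Regimes.** With $K = 3$, states in ascending $\beta$ order are labelled
  hypo-, intermediate- and hypermethylated.
* **Hypomethylated loci** are segments whose count-weighted mean
  methylation does not exceed 20% — the boundary is inclusive
  (`mean <= 0.20`), reading "does not exceed" literally. The same threshold
  can be applied to any sample's table over a fixed segmentation, which is
  how cross-cell-type comparisons work.
* **Sample-specific loci**: a locus is specific to a focal sample when it
  is hypomethylated there but in no other sample, or hypomethylated in
  every other sample but not the focal one (strict "all others" on both
  sides; loci missing data in any sample are never flagged).
* **Enrichment** against a feature set (promoters, CpG islands, CTCF
  sites) counts features overlapped by at least 1 bp and compares with a
  permutation null that re-places each locus uniformly at random within its
  own chromosome, lengths preserved, overlaps among placed loci allowed —
  the simplest null compatible with "expected at random"; a flag allows
  cross-chromosome placement. The z-score is undefined (reported `NA`)
  when the null is degenerate.

## Descriptive statistics

`global_methylation()` is count-weighted by default (total methylated calls
over total calls), which suits sparse single-cell depth; a per-site mean is
available behind a flag. `bin_methylation()` tiles chromosomes from
coordinate 1 in fixed windows (default 5 kb, at least 3 covered CpGs per
usable bin); `correlate_samples()` computes Spearman correlation over
shared non-missing bins. `feature_methylation()` profiles intervals and
attaches a distribution summary (histogram plus the fractions below 40% and
above 60%, where hypo- and hypermethylated loci separate) for spotting the
bimodality typical of promoters and CpG islands.

For tandem repeats that defeat genomic alignment, `build_repeat_references()`
constructs the four bisulfite-converted reference variants of a monomer
(top/bottom strand × methylated/unmethylated, all written against the top
strand; CpG context is evaluated circularly because the monomer is tandem),
and `classify_repeat_reads()` assigns reads to the methylated or
unmethylated pool by their best ungapped match against the tandem
concatenation, trying each read in both orientations. Ties (e.g. for a
CpG-free monomer, whose variant pairs coincide) and sub-threshold scores
(default minimum match fraction 0.9) stay unassigned. This scorer is
deliberately self-contained and exact; it is not a general-purpose aligner.

## The synthetic-data generator

`simulate_methylome()` draws from the model itself: geometric inter-CpG
gaps (mean 100 bp — the memoryless stand-in for CpG spacing), hidden states
from the distance-decay chain ($d_0 = 1250$ bp), depth from a Poisson
(mean 3) truncated at 8 — the ceiling implied by one diplotene nucleus,
four chromatids × two converted strands, so generated tables pass the
coverage-artifact filter untouched — and binomial counts at regime means
0.05/0.50/0.85. The defaults produce ~50,000 CpGs over five 1-Mb
chromosomes, matching the scale at which the package's own checks run.
Everything is byte-reproducible under a seed.

`simulate_multisample()` shares one hidden backbone across samples and
plants sample-specific loci by forcing the focal sample and the others into
opposite extreme regimes inside each planted window. Each window gets a
collar (default 2 kb) of the opposite regime in *all* samples; without it a
reverse-case window would merge into the surrounding shared regime and be
undetectable by construction, since segment boundaries are decoded from the
focal sample alone.

What the generator deliberately does **not** emulate: CpG-island spacing
structure (real gaps are far from geometric), sequence-driven depth biases,
chromosome-scale methylation trends, bisulfite non-conversion errors, and
read-level data. Passing tests on this generator therefore demonstrate
correctness of the machinery under the model's own assumptions, not
performance on real libraries.

## Numerical choices

* Betas are clamped to $[10^{-6}, 1 - 10^{-6}]$ so log-emissions stay
  finite.
* EM initializes $\beta$ at evenly spaced quantiles (10%…90%) of the
  *shrunken* per-site fractions $(m_t+1)/(n_t+2)$ — raw fractions are
  almost all 0 or 1 at single-cell depth and would pin the initial values
  to the boundary; $\pi$ starts uniform. The procedure is deterministic
  (no random restarts), so a seed passed to `methyl_hmm()` is recorded but
  unused.
* Convergence: relative improvement of the weighted log-likelihood below
  `tol` (default $10^{-4}$) or 200 iterations.
* Scaled (not log) forward–backward with a per-site shift of the weighted
  log-emissions, so the $(n_t+2)$ power cannot underflow; the shift is
  absorbed into the returned log-likelihood exactly. The rank-1 structure
  of the transition matrix gives $O(TK)$ recursions; these loops are
  compiled (Rcpp).
* States are returned in ascending-$\beta$ canonical order, which removes
  label switching.
* Duplicate positions in input are a hard error by default (they indicate
  upstream mistakes); `dedup = "sum"` merges them on request. Unsorted
  input is sorted with a notice.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data:
model selection and the hypomethylation summary use the default ~50k-CpG
simulation (three seeds for the selection verdict); parameter-recovery
checks use 20 replicates at the same scale; decoder correctness is checked
against exhaustive path enumeration on series of up to 12 sites; everything
else runs on toy tables of a few dozen sites.

## Limitations

* The depth-weighted estimator's outward bias at extreme regimes (above).
* The distance kernel is shared genome-wide; there is no per-chromosome or
  per-compartment $d_0$.
* Emissions are binomial: overdispersion (e.g. allele-specific methylation)
  is not modelled.
* The repeat-read classifier is exact/ungapped and suited to short tandem
  monomers, not to long or diverged repeats.
* Non-CpG contexts are out of scope; CX reports are filtered to CpG rows.
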