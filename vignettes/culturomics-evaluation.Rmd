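---
title: "Evaluating culturomics experiments: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating culturomics experiments: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultureval)
```

# The problem

High-throughput culturomics transfers microorganisms from a complex
clinical biofilm (the *inoculum*) onto arrays of colonies grown on one or
many media (*prints*), and asks: how much of the original community did
cultivation recover?  Answering that requires a consistent quantitative
pipeline — aggregating amplicon feature tables across taxonomy ranks,
applying abundance cut-offs, comparing diversity, ranking media by
complementarity, and (for isolate identification) classifying infrared
spectra of the cultured organisms.  `cultureval` implements that pipeline
end to end and pairs it with a synthetic-data generator whose ground truth
is known, so every stage can be validated without sequencing data.

# Recovery scoring

Both the inoculum and the print group are relative-abundance profiles at a
chosen rank.  A feature is **eligible** when its relative abundance reaches
the inoculum cut-off `inoc_cutoff`; it is **recovered** when, in addition,
it reaches `print_cutoff` in at least one print sample.  The statistic is

$$\mathrm{recovery} = \frac{|\text{eligible} \cap \text{detected}|}{|\text{eligible}|}.$$

Two design questions are genuinely open and we fixed them as follows:

* **Pooling across inoculum replicates.**  Eligibility uses the *maximum*
  abundance over inoculum samples (a feature that reached the cut-off in
  any replicate counts).  This is the inclusive reading of "reached at
  least x% in the inoculum"; the alternative — the mean profile — is
  available via `pooling = "mean"`.
* **The print-side detection threshold.**  No universal convention exists;
  we default to the same value as the inoculum cut-off (symmetric
  thresholds), exposed as `print_cutoff`.

An empty eligible set yields an `NA` fraction rather than 0: "no feature
was abundant enough to score" is not the same finding as "nothing was
recovered".  Enrichment is the mirror image: features below the detection
cut-off in *every* inoculum sample (or absent) that appear above it in at
least one print.

Class-level shifts between sample groups use the two-sided Mann–Whitney U
test with Bonferroni correction across the classes tested.  The exact path
enumerates all $\binom{n_1+n_2}{n_1}$ group assignments (used when both
groups have at most 8 samples — it is exact under ties, which abundance
data always have); larger groups use the tie-corrected,
continuity-corrected normal approximation.  The two paths agree to about
0.01 in p at the crossover size, which is the intrinsic accuracy of the
normal approximation there, not a numerical defect.

The cell input/output ratio bound treats a printed micro-colony as a
scaled-down sphere: the reference colony yield is multiplied by
$(r_\text{print}/r_\text{ref})^3$ and divided into the maximal droplet
input.  With the conventional inputs (20–200 cells per droplet, $2\times
10^9$ cells per 5 mm reference colony, 0.5 mm prints) the bound is
$10^{-4}$.

# The diversity suite

`diversity_suite()` reports, per sample: richness $S$ (Hill $N_0$),
Margalef $d = (S-1)/\ln N$, Pielou $J' = H'/\ln S$, Brillouin
$H = (\ln N! - \sum_i \ln n_i!)/N$ (via log-gamma), Fisher's $\alpha$
(root of $S = \alpha\ln(1+N/\alpha)$, solved by bracketed root finding on
$[10^{-8}, 10^8]$ — the defining function is monotone, so no derivative is
needed; when $S = N$ no finite root exists and `Inf` is returned), Shannon
$H'$ in natural log, both Simpson variants ($1-\lambda$ with
$\lambda = \sum p_i^2$, and the unbiased $1-\lambda'$ with
$\lambda' = \sum n_i(n_i-1)/(N(N-1))$ — figures in this literature use
either, so both are reported and callers must name one), the Hill numbers
$N_1 = e^{H'}$, $N_2 = 1/\lambda$, $N_\infty = 1/p_\text{max}$ and their
ratios, Hurlbert's rarefaction
$ES(m) = \sum_i [1 - \binom{N-n_i}{m}/\binom{N}{m}]$ (log-gamma
evaluation; $ES(100)$ is the conventional proxy for picking 100 colonies),
and Good's coverage $1 - F_1/N$.

Undefined quantities on degenerate input ($J'$, $N_{10}'$, $N_{21}'$ for a
single-feature sample) are explicit `NA` sentinels.  Rarefaction to fixed
depth is an exact multivariate-hypergeometric subsample; samples below the
target depth are dropped with a warning rather than failing the table,
mirroring the practice of excluding individual low-depth libraries.  The
default depth of 6,070 reads is the evaluation convention this pipeline
standardizes on.

# Beta diversity

The enforced order is *standardize by feature maximum → fourth-root
transform → Bray–Curtis*, with similarities kept on the 0–100 scale.
Group-average (UPGMA) clustering runs on $100 - S$; flat clusters cut the
tree at a similarity threshold, 60 by default.  Bray–Curtis and the
average-linkage agglomeration are delegated to `vegan` and
`stats::hclust`; the test suite verifies both against hand-rolled
brute-force oracles.

Non-metric MDS is implemented in the package because we need seedable
restarts and an inspectable stress trace: Kruskal's stress-1
$\sqrt{\sum(d-\hat d)^2/\sum d^2}$ is minimized by steepest descent with a
backtracking line search (stress is guaranteed non-increasing within a
restart), with disparities $\hat d$ from pool-adjacent-violators monotone
regression under the primary tie treatment.  The first start is the
classical-scaling solution, the rest are random; 20 restarts by default.
On test data the optimizer matches or beats `vegan::monoMDS` optima.
Vector overlays report the Pearson correlation of each variable with each
ordination axis; constant variables map to zero-length vectors with a
warning.

# Media complementarity

Per-medium recovered sets (against the shared eligible universe) feed
three views: greedy stepwise ranking — each step adds the medium
contributing the most not-yet-covered features, ties broken
lexicographically on the label so results are deterministic; exclusive
UpSet intersection counts, which partition the union; and cumulative
coverage curves along any ordering.  Greedy set cover is step-wise optimal
but not globally optimal, so `exhaustive_rank()` (≤ 12 media) quantifies
the gap on small designs.

# FT-IR preprocessing and classification

Spectra move through an enforced three-stage pipeline.  Baseline
correction subtracts the straight line through the spectrum's endpoints:

$$\text{slope} = \frac{a_n - a_1}{w_n - w_1},\qquad
  \text{offset} = a_1 - \text{slope}\cdot w_1,\qquad
  a'_k = a_k - (w_k\,\text{slope} + \text{offset}),$$

so $a'_1 = a'_n = 0$ exactly and re-application is a no-op.  Vector
normalization mean-centers and scales to unit Euclidean norm:

$$a''_k = a'_k - \tfrac1n\sum_j a'_j,\qquad
  a'''_k = a''_k \big/ \sqrt{\textstyle\sum_j (a''_j)^2},\qquad
  \sum_k (a'''_k)^2 = 1.$$

Jointly the pipeline is invariant to any added linear ramp and to positive
intensity scaling — the property the test suite checks on a thousand
random spectra.  Analysis restricts to the fingerprint (900–1800 cm⁻¹)
and CH-stretching (2800–3000 cm⁻¹) regions, concatenated for
classification.

Classification is Fisher LDA: maximize the between- to within-class
scatter Rayleigh quotient; at most $c-1$ discriminant axes, scaled so the
pooled within-class variance along each axis is 1, making
nearest-class-mean assignment Mahalanobis-equivalent under uniform priors
(class sizes are balanced by design here).  With more grid points than
spectra the within-scatter is singular; the default regularization
projects onto the principal components explaining ≥ 99% of variance
first, with a ridge alternative (`lambda` on the within-scatter diagonal).
Whether published pipelines fed LDA raw normalized spectra or PCA scores
is typically unstated; we declare PCA-reduction as this package's default
rather than inferring anyone else's choice.  Performance is assessed by
stratified, seeded 5-fold cross-validation; the accuracy CI is the Wilson
score interval, which remains sensible at accuracy 1 where the Wald
interval collapses.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; real data differ in ways the tests therefore cannot vouch for.

* **Inoculum**: feature abundances are ranked log-normal draws
  (`lognormal_sigma = 1.5`), the standard shape for host-associated
  communities; no generative model is established for clinical biofilms,
  so this is a convention, not an inference.  Lineages come from recursive
  random branching over domain→genus.
* **Medium effects** factorize into a hard survival indicator and a soft
  log-normal growth bias (`bias_sdlog = 0.5`).  Survival is hierarchical:
  a feature is culturable at all with probability 0.85, and a culturable
  feature survives each medium independently with probability 0.5.  The
  culturability level exists because fully independent per-medium survival
  would make virtually every feature recoverable somewhere on a 16-medium
  panel, which real communities with genuinely unculturable members do not
  show.
* **Reads** are one multinomial draw per print at a depth sampled
  uniformly from 6,640–26,728, the realistic per-sample range; column
  totals equal the depth exactly.
* **Spectra** are Gaussian peak mixtures (4 fingerprint + 2 CH peaks per
  class) times a random intensity scale, plus a random linear baseline and
  Gaussian noise on a 2 cm⁻¹ grid over 525–4000 cm⁻¹.  `disjoint = TRUE`
  carves the regions into private per-class bands — the separable design
  used for classifier sanity checks.

What the generator does **not** emulate: phylogenetically correlated
medium effects, 16S copy-number and colony-size biases (deliberately
uncorrected, matching practice), chimeras and other upstream sequencing
artifacts, spatial structure of colony arrays, and instrument-specific
spectral artifacts (ATR penetration depth, water vapour bands).  Passing
tests demonstrate the *machinery* is correct under known truth, not that
any particular biological recovery figure will be reproduced.

# Numerical choices and degenerate inputs

* Fisher's $\alpha$: bisection-bracketed root on $[10^{-8}, 10^8]$,
  tolerance $10^{-10}$.
* Brillouin and $ES(m)$ via log-gamma; no factorials are formed.
* $ES(m)$ with $m > N$ is capped at $N$ with a warning; $ES(N) = S$.
* All-zero count vectors, zero-total samples, empty eligible sets,
  constant spectra and degenerate grids raise errors or `NA` sentinels
  with the offending sample named.
* Greedy and UPGMA tie-breaks are deterministic (lexicographic label,
  `hclust` ordering) so fixed seeds reproduce byte-identical outputs.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state afterwards.

# Problem sizes used in the validation suite

The bundled tests and the analysis scripts run the study-scale design: 200
features, 16 media, print depths around $10^4$ reads, 5 spectral classes
with 8 replicates (40 spectra, matching the order of magnitude of a
few-hundred-spectrum training set), 200-seed parameter-recovery sweeps and
a 1,000-spectrum preprocessing-identity sweep.  These sizes were chosen as
the smallest at which the sampling-noise tolerances (binomial bands,
3-standard-error Monte-Carlo checks) are meaningful.

# Known limitations

* Recovery matching is by feature id / lineage string; reconciling renamed
  taxa across nomenclatures is the caller's responsibility.
* The nMDS optimizer, like all stress minimizers, can land in local optima;
  restarts mitigate but do not eliminate this.
* Bonferroni is the only multiple-testing correction offered, matching the
  reporting convention this pipeline standardizes on; no FDR option.
* No phylogenetic diversity (UniFrac, Faith's PD) and no
  PERMANOVA/ANOSIM/SIMPER — outside this pipeline's scope.
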