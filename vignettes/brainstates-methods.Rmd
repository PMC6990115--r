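---
title: "Methods: supervised Tucker3 discrimination of brain states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised Tucker3 discrimination of brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

## The problem

Two experimental brain states — a resting baseline and a focused-attention
meditation block — are measured as region-of-interest (ROI) BOLD time
series: for each of $n$ subjects, two blocks of $T$ volumes over $J$
regions. Mass-univariate contrasts of single functional metrics often find
nothing at these sample sizes; the question is whether a *combination* of
regions and metrics separates the two states. The pipeline implemented here
answers that with a supervised three-way component model fitted to a
subjects $\times$ regions $\times$ metrics feature array, followed by
permutation inference on the component loadings.

## From time series to features

For every subject-condition block we compute a functional connectivity
matrix of Pearson correlations between region time courses, mapped to
Fisher-z units ($z = \mathrm{atanh}(r)$, with $r$ clamped to
$\pm(1-10^{-7})$ so duplicated signals stay finite; only the rank order near
the top matters downstream). The matrix is binarized by **cost
thresholding**: at cost $c$, the $m = \mathrm{round}(c\,J(J-1)/2)$ strongest
off-diagonal pairs become edges (rounding half away from zero; ties at the
cutoff break by ascending $(i,j)$ order, which makes edge sets nested across
costs and every output deterministic). At $J = 116$ and $c = 0.100$ this
keeps 667 of the 6{,}670 possible connections.

Four regional features enter the analysis, in a fixed serialized order:

* **degree centrality** — the number of neighbours;
* **betweenness centrality** — the fraction of shortest paths through a
  node, normalized by $(J-1)(J-2)/2$ so it lies in $[0,1]$ (the study-scale
  analysis is scale-free after standardization, but the convention is fixed
  for reproducibility);
* **clustering coefficient** — the Watts–Strogatz local density
  $2e_v/(k_v(k_v-1))$, with 0 for degree $< 2$;
* **fALFF** — the fraction of spectral amplitude (DFT modulus, after mean
  and linear-trend removal, DC excluded) inside the low-frequency band,
  default 0.008–0.09 Hz on the grid $k/(T\cdot\mathrm{TR})$ with inclusive
  endpoints. Band-edge variants (0.01–0.1 Hz appear in parts of the
  literature) are a configurable argument. fALFF here is computed directly
  on the region time course; voxelwise computation with within-region
  averaging would require voxel data the pipeline does not ingest.

Disconnected pairs contribute zero to global efficiency; neighbourhoods of
degree $< 2$ contribute zero to local efficiency — the common conventions.

## Choosing the cost threshold

A single cost is chosen from the grid 0.050–0.500 in steps of 0.025 (19
settings) by three criteria:

1. **Small-world feasibility.** A cost survives if the group-mean global
   efficiency of the observed networks lies strictly between edge-matched
   ring lattices and degree-matched rewired references
   ($E_{\text{lattice}} < E_{\text{obs}} < E_{\text{random}}$, means over
   `n_realizations = 20` rewirings per network; the count is a compute/
   precision trade-off the user can raise).
2. **Similarity to average characteristics.** Per block, the degree vector
   at each feasible cost is correlated with the across-cost average degree
   vector; scores average over blocks. Higher is better.
3. **Community-count stability.** Per condition and cost, the number of
   communities (greedy modularity, resolution $\gamma = 1$) per participant;
   the sample SD (denominator $n-1$) across participants, averaged over the
   two conditions. Lower is better.

How criteria 2 and 3 combine into one choice is not canonical; the default
here ranks feasible costs by similarity (descending) and stability SD
(ascending) and picks the minimal rank sum, ties resolved toward the
smaller cost (weak connections are the usual argument for preferring lower
costs). `rule = "similarity_first"` and `"stability_first"` are provided.
Criteria 2–3 are evaluated on the feasible subset of the grid, matching the
reading that the averaging range is the feasible range.

Community detection is a deterministic greedy agglomeration of
resolution-parameterized modularity
$Q(\gamma) = \sum_c (e_{cc} - \gamma a_c^2)$: merge the connected pair with
the largest gain, lexicographic tie-breaks on community labels, return the
partition with maximal $Q$ along the merge path. The deterministic,
seed-free merge order is the point — stochastic implementations would make
the stability criterion itself unstable. $\gamma > 1$ finds smaller
modules; 1 is the neutral default.

## The supervised Tucker3 model

The features form a three-way array $X$ ($I = 2n$ observations $\times J$
regions $\times K = 4$ metrics). Matricized with region index fastest
(column $(k-1)J + j$), the Tucker3 model is

$$X_{I,JK} = U\, Y_{G,QR} (C \otimes B)^\top + E_{I,JK},$$

with $U$ the binary row-stochastic class indicator ($G = 2$ known
conditions — the *supervised* variant: $U$ is never optimized), $B$
($J \times Q$) and $C$ ($K \times R$) column-orthonormal loading matrices,
and $Y$ the core centroid array. Defaults $Q = 2$, $R = 1$ project every
observation into a two-dimensional component space with a single metric
combination. The objective is the squared Frobenius residual.

With $U$ fixed, the optimal core given $(B, C)$ is
$(U^\top U)^{-1} U^\top X (C \otimes B)$, and minimizing the residual is
equivalent to an orthogonal Tucker decomposition of the weighted class-mean
tensor $W = (U^\top U)^{-1/2} U^\top X$ — a $2 \times J \times K$ problem.
It is solved by higher-order orthogonal iteration (HOOI). Alternating
schemes of this kind can stall in local optima on unstructured data
(measured at roughly 1–2% of small random instances with a plain HOSVD
start), so the iteration is run from the HOSVD initialization (leading
singular vectors of $W$'s mode unfoldings) *plus* one deterministic basis
initialization of $C$ per metric, keeping the best objective — seed-free
multi-start rather than random restarts, preserving bit reproducibility.
Within each run the objective is non-increasing (asserted in tests);
convergence is declared when the loss change falls below
`tol = 1e-9` $\times \lVert X \rVert^2$, with `max_iter = 500` as a
safety stop. Inside permutation loops the refits use the single-start fast
path; observed and permuted data go through the identical procedure, which
is all exchangeability requires.

Identifiability: with $Q = 2$ the individual columns of $B$ are
rotation-ambiguous within the fitted subspace. Determinism is imposed by
ordering columns by explained norm and flipping signs so each column's
largest-magnitude element is positive; *inference uses absolute loadings
only*, so these conventions cannot change any conclusion.

**Standardization.** The four metrics live on incommensurate scales (degree
counts versus $[0,1]$ coefficients); an unstandardized fit is dominated by
degree. Each (region, metric) column is therefore z-scored across
observations by default (`standardize = TRUE`), with zero-variance columns
set to zero under a warning. The raw mode is retained as a flag because the
appropriate preprocessing of $X$ is a genuinely open choice; the paired
t-test baseline is invariant to it, and the permutation test is run on the
same tensor the model was fitted to.

Component scores come in two modes: **raw**, $X(C \otimes B)$, one point
per observation (used for plots and the score condition test), and
**centroid**, $U(U^\top U)^{-1}U^\top X (C \otimes B)$, constant within
class (the model's fitted centroids). Class means of raw scores equal the
centroid scores exactly.

## Inference

**Permutation test on loadings.** Condition labels are permuted
(`within_subject` default: each subject's pair of labels swaps
independently with probability 1/2, respecting the paired design; `free`
relabeling is available since the pairing assumption is a choice), the
model refitted, and absolute first-component region and metric loadings
recorded. $p = (1 + \#\{|\lambda^*| \ge |\lambda_{\text{obs}}|\})/(n_{\text{perm}}+1)$
— the +1 keeps $p \ge 1/(n_{\text{perm}}+1)$ and is mildly conservative.
Regions and metrics are tested separately at raw $p < \alpha = 0.05$
(no multiplicity correction, the common reporting convention for loading
tests; BH-adjusted q-values are reported alongside for users who want
them). The default is `n_perm = 10000`; the test suite
and acceptance script use 999 to keep runtimes proportionate, which changes
only the resolution of the p-values.

**Score condition test.** A paired t-test per component on raw scores —
the natural choice for the paired design, quantifying whether a component
separates the two conditions. All-zero paired
differences return $t = 0, p = 1$; zero-variance nonzero differences are
degenerate and raise an error.

**Baseline.** Paired t-tests on every (region, metric) cell with
Benjamini–Hochberg correction across all $J \cdot K$ tests at $q < 0.05$ —
the conventional approach the component model is compared against.

**Overlap across costs.** When the analysis is repeated over the 19-cost
grid, each region's overlap ratio is the fraction of costs at which it was
selected, with sub-range ratios for the lower (0.050–0.225, 8 costs) and
higher (0.250–0.500, 11 costs) halves.

## Synthetic data: what it emulates and what it does not

Matched empirical recordings cannot be bundled with the package, and no
generative model for such data is settled; both generators below are
labeled stand-ins with known ground truth, built so that every downstream
stage is testable offline.

**Tensor-level generator** (`simulate_feature_tensor`) inverts the Tucker3
model directly: $B$'s first column is unit-uniform on a planted region set,
$C$ is one-hot on a planted metric, class centroids sit $\pm\delta/2$ apart
along component 1, and i.i.d. Gaussian noise of SD $\sigma$ is added. A
smaller class-shared second component (weight $\delta/4$, supported on the
complementary regions) makes the two-column region subspace identifiable in
the noiseless case; at $\delta = 0$ the tensor is pure noise — an exact
null for calibration studies. Defaults mirror the study layout: 29
subjects, 116 regions, 4 metrics.

**Time-series generator** (`simulate_timeseries_dataset`) draws each block
from a zero-mean multivariate Gaussian with block-structured correlations:
the effect regions form one block, remaining regions consecutive blocks of
8; within-block correlation `rho0 = 0.1` everywhere, raised to
`rho1 = 0.9` inside the effect block in the meditation condition (a strong,
unambiguous planted effect — after thresholding, the effect block becomes
near-clique and its clustering coefficients rise). Between-block
correlations are seeded jitter of SD 0.002 — large enough to break ties,
small enough that positive semi-definiteness survives the `rho1 = 0.9`
block, and verified at build time (non-PSD parameter combinations are
rejected by name). Blocks are generated independently per subject and
condition (the analysis treats them as separate observations; no
carry-over). Signals are then spectrally shaped by one common filter
scaling out-of-band DFT amplitudes so the expected in-band fraction equals
`band_power_fraction = 0.8` — band-limited like preprocessed BOLD with
residual broadband noise, and a single common filter provably leaves the
cross-region correlation structure intact while giving exact control of the
fALFF ground truth. Defaults: $T = 120$ volumes at TR $= 2.5$ s (a 5-minute
block), band 0.008–0.09 Hz.

Neither generator models hemodynamics, physiological noise, motion,
spatial structure, or voxel-level data. Passing tests on these inputs
demonstrate that the *pipeline* recovers what it assumes — planted
covariance effects under Gaussianity — not that real meditation data would
behave this way.

## Numerical choices and degenerate inputs

* Fisher-z clamp at $|r| = 1 - 10^{-7}$; zero-variance regions error by
  name.
* Edge-count rounding: nearest integer, half away from zero (no rounding
  rule is canonical; this one is documented and tested).
* Detrending before fALFF: without it, trend leakage dominates the lowest
  bins. One interaction worth knowing: a pure sinusoid whose phase has a
  nonzero projection on the linear trend (e.g. a sine over this window)
  re-acquires a small broadband component when the fitted trend is
  subtracted, reading fALFF $\approx 0.92$ rather than $1$; a cosine-phase
  tone shows none. This is a property of detrended spectra generally, not
  of this implementation.
* HOOI convergence tolerance is relative to $\lVert X\rVert^2$, so a loss
  approaching zero (noiseless data) terminates cleanly.
* Degenerate similarity correlations (constant degree vectors) contribute 0
  with a warning; zero-variance t-test cells get $p = 1$ with a warning.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so every result in this package is bit-reproducible given a seed.

## Problem sizes used in the shipped checks

The test suite and acceptance script exercise the study-scale configuration
(29 subjects, 116 regions, 120 volumes) for the fit, recovery and
calibration checks; permutation counts are 999 and Monte-Carlo batch sizes
(500 null tensors, 50 end-to-end datasets, 1000 white-noise replicates)
were chosen to give comfortable Monte-Carlo precision for the rates being
asserted. Oracle-equivalence checks enumerate all graphs on up to 6 nodes
exhaustively plus 200 random graphs on up to 8 nodes.

## Known limitations

* Only binary (unweighted) networks; no partial correlation, coherence or
  phase-based connectivity; no weighted metrics.
* The supervised variant only: the general T3Clus alternation over $U$ is
  out of scope, as are Tucker2/PARAFAC variants and missing-data handling.
* Regional (not voxelwise) fALFF.
* The baseline "flags nothing" behaviour under the null is a statement
  about BH at $q<0.05$, whose any-rejection probability is itself
  $\approx \alpha$; on discrete, non-normal graph metrics at $n = 29$ the
  extreme t-tail is mildly inflated (measured $\Pr(p<10^{-4}) \approx
  2\times$ nominal), so occasional single false positives across hundreds
  of cells are expected.

## A worked example

```{r example, eval = FALSE}
library(brainstates)

sim <- simulate_timeseries_dataset(timeseries_sim_spec(seed = 11))
feats <- compute_features(sim$blocks, cost = 0.225)
tensor <- standardize_tensor(assemble_feature_tensor(
  feats[, c("subject_id", "condition", "region", "metric", "value")]))

fit <- t3clus(tensor)                       # G = 2, Q = 2, R = 1
perm <- permutation_test(tensor, n_perm = 999, seed = 5)
tidy(perm, "metrics")
score_condition_test(component_scores(fit, "raw"))
autoplot(fit)
```
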