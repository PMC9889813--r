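---
title: "Detecting spatial clusters of low birth weight and preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatial clusters of low birth weight and preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natalclust)
```

# The problem

Birth outcomes are recorded at the individual level but questions about
geographic inequity are asked at the area level: are there municipalities
where low birth weight (LBW, < 2500 g) or preterm birth (PTB, < 37 completed
weeks) is genuinely more common, after accounting for the maternal age
structure and for the enormous spread in municipality size? A naive
municipality-level rate map is dominated by noise — a village with 12 births
and one LBW baby shows an 8.3% "rate" that means almost nothing — while a
formal cluster test must distinguish chance aggregation from real elevation.
`natalclust` packages the standard chain for this problem: outcome
classification, age standardization, spatially structured empirical Bayes
smoothing for mapping, and two complementary cluster tests (a global one and
a local one) with Monte Carlo inference.

# Cohort and outcome model

Each singleton live birth is classified by two binary outcomes whose
crossing yields four exclusive groups: `LBW_pre`, `LBW_term`, `NBW_pre`,
`NBW_term`. The thresholds are strict (`< 2500 g`, `< 37 weeks`), so a
2500 g, 37-week baby is normal-weight and term, and LBW always partitions
exactly into its term and preterm components — an identity asserted in the
tests. Multiple births are excluded (their LBW risk is structurally higher
and would confound spatial contrasts); records missing any of municipality,
birthweight, gestational age or maternal age are dropped and tallied.
Gestational ages outside 20–45 completed weeks are treated as missing: these
are implausible for a live birth and almost certainly coding errors.

Maternal age enters twice, at two resolutions:

* nine right-closed classes `<=15, (15,20], ..., (45,50], >=50` for
  standardization (fine enough to absorb the J-shaped age–risk profile);
* three reporting strata `<=20, (20,35], >35` for summary tables and for
  stratified cluster analyses, where the 9-class tables would be too sparse
  within a stratum.

# Rates and standardization

Two standardizations serve two purposes:

* **Direct** ASR (a weighted sum of stratum rates with reference weights
  `W_a`) feeds the maps: it answers "what would this municipality's rate be
  if it had the reference age structure". When a small municipality has no
  births in a stratum, its denominator is imputed with 0.0001 (numerator 0),
  so the stratum contributes a zero rate rather than a division failure.
  The imputed-zero reading keeps the ASR finite and unbiased at zero; the
  alternative (imputing the *rate*) would inflate empty strata.
* **Indirect** expected counts `E_i = sum_a n_ia rho_a`, with `rho_a` the
  pooled stratum rates, feed the cluster statistics, which need counts, not
  rates. `E` is multiplicatively calibrated so `sum(E) = sum(O)` exactly —
  a no-op when `rho` comes from the same data, but it makes externally
  supplied reference rates safe and lets every downstream statistic assume
  calibration.

Display rounding is half-up to two decimals (as printed tables round);
all internal computation is full precision.

# Local empirical Bayes smoothing

Raw ASRs for small municipalities are wildly unstable. The smoother is the
Marshall-type *local* estimator: each municipality is shrunk toward the
mean of its spatial neighborhood (not the global mean — spatial risk
structure is exactly what we want the map to keep). With
`D_i = N(i) ∪ {i}`:

* neighborhood mean `m_i = Σ_j asr_j n_j / Σ_j n_j`,
* local variance `s²_i = Σ_j n_j (asr_j − m_i)² / Σ_j n_j`,
* between-area component `A_i = max(0, s²_i − m_i / n̄_i)` (moment
  estimator; negative values truncated to zero, giving full shrinkage),
* weight `w_i = A_i / (A_i + m_i / n_i)` and
  `ebsir_i = m_i + w_i (asr_i − m_i)`.

Two consequences are asserted as invariants: `ebsir` always lies between
the raw rate and the neighborhood mean, and `w_i` grows with the
municipality's own denominator (big cities keep their own rate, villages
borrow). Including the focal unit in `D_i` guarantees a defined `m_i` even
when all neighbors are empty; a truly isolated unit is returned unshrunk
with a warning. The neighborhood comes from queen contiguity when polygons
are available, else k-nearest neighbors (k = 8, union-symmetrized,
distance ties broken by ascending id); both are exposed, since either is a
defensible reading of "spatial neighborhood" and the choice is a
configuration item. A global variant (`global_eb()`) is provided for
comparison. Maps class the smoothed surface into quantiles (default 5,
ties to the lower class).

# Cluster inference

**Tango's C** tests globally for *any* clustering: a quadratic form in the
centered case shares under an exponential distance-decay kernel
`exp(−d/λ)`. λ is the kernel's clustering scale; the default is the median
nearest-neighbor distance, a data-driven scale that matches the resolution
of the municipality system. Calibration is by Monte Carlo rather than the
chi-squared approximation: replicates are already needed for the scan, and
the Monte Carlo null is exact at any sample size.

**The circular Poisson scan** locates clusters. The window family takes
every municipality as a center and grows by centroid distance until the
window would exceed half of all births (the conventional cap; configurable).
Each window is scored by the one-sided high-rate Poisson log-likelihood
ratio; only elevated-risk windows are of interest here (a low-rate mode
exists behind a flag). Reported clusters are the greedy pairwise-disjoint
top three — most/second/third likely cluster — and each one's p-value
compares its LLR against the null distribution of the *maximum* LLR over
all windows, so secondary p-values are conservative in the usual way.

The Monte Carlo null redistributes the observed case total multinomially
with probabilities `E/E+` — conditioning on `O+` is the standard scan null
and is what "resampling with replacement" of case locations amounts to.
p-values use the rank formula `(1 + #{max LLR_sim ≥ llr}) / (nsim + 1)`
with floor `1/(nsim+1)`; with 999 replicates the floor prints as
"< 0.001". The reported relative risk is `O/E` (this is what published
cluster tables print, verified to two decimals on several rows); the
Kulldorff-style indirect ratio, which contrasts inside vs outside rate, is
also stored.

The per-replicate maximization runs in C++; the observed-window
likelihoods are computed in R and a test feeds the observed counts through
the C++ kernel to pin the two routes together. On exact lattices many
centroid distances tie, and the deterministic id tie-break then *defines*
the window family — so the zone set on a perfect grid is reproducible but
not label-invariant; on real (or jittered) geometries ties have measure
zero.

# The synthetic registry

Real vital-registration microdata is access-restricted, so the package
carries its own generator, which is first-class, tested code:

* municipality systems as planar-km lattices (default 15 × 15, 10 km
  spacing), optionally jittered; exact lattices also emit square polygons
  so queen contiguity is exercised;
* denominators `~ log-normal(median 500, sdlog 1.5)`, spanning roughly
  four orders of magnitude — the small-island-to-metropolis spread that
  makes smoothing necessary;
* a maternal age profile whose reporting-strata shares (≈2.2% ≤20,
  ≈76.6% (20,35], ≈21.2% >35) echo national birth statistics, used both as
  generator profile and default standardization reference;
* baseline group rates with a J-shaped age profile scaled so pooled shares
  are 5.23% LBW term, 3.00% LBW pre, 1.74% NBW preterm (hence LBW 8.23%,
  PTB 4.74%);
* planted circular clusters multiply group rates by a configurable relative
  risk, specified by radius or by nearest-unit count (a circle centered on
  a lattice point cannot cover an arbitrary unit count, so the `n_units`
  form exists for exact-size experiments); overlapping clusters multiply;
* cases are drawn per stratum (multinomially across the four groups at
  record level, or Poisson truncated at the denominator at count level),
  and record-level output carries birthweights and gestational ages drawn
  within each group's defining range, so aggregating the records through
  the cohort module reproduces the count tables exactly — asserted in the
  tests.

What the generator does *not* emulate: real administrative geographies
(coastlines, enclaves, genuinely irregular polygons), secular trends across
years, nationality structure, or correlation between municipality size and
risk. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under a Poisson/multinomial world with circular
clusters — not that any particular real-world cluster is reproducible.

# Calibration and power, as run in the tests

The acceptance suite measures, at fixed seeds:

* exact agreement of the scan MLC (LLR and member set) with exhaustive zone
  enumeration on 50 small random instances;
* type-I error of the MLC at α = 0.05 under a uniform risk surface on the
  default 225-municipality system (200 replicates, 199 null sims each):
  the rejection rate must land in the binomial band [0.02, 0.09];
* recovery of a planted relative-risk-2.0 cluster (7 of 225 units, ≈40
  expected in-cluster cases): member-set Jaccard ≥ 0.6 in ≥ 80% of 100
  replicates, with the MLC's O/E averaging in [1.6, 2.4] — slightly below
  2.0 because calibration spreads the excess cases into every `E_i`;
* Tango's statistic against a brute-force double sum (1e-12), its zero at
  proportional shares, and the Monte Carlo p-floor;
* the smoothing invariants above plus a 3-unit hand-computed oracle;
* byte-identical pipeline reruns under a fixed seed.

Problem sizes (225 municipalities, 199–999 null replicates, 100–200 outer
replicates) were chosen as the smallest instances at which these binomial
bands are meaningful; they run in a couple of minutes on one core.

# Numerical and degenerate-input choices

* `x log x → 0` at zero counts in the LLR; windows whose expected count is
  zero (possible in sparse strata) carry no signal and score 0.
* Windows are ranked by LLR with deterministic tie-breaks
  (center id, then window size); Monte Carlo draws are `rmultinom` under a
  user seed, so every result is bit-reproducible.
* `nsim = 0` runs the scan without inference (p = NA) for location-only
  experiments; `nsim < 19` is refused for the Tango test since α = 0.05
  would be unresolvable.
* Empty input, all-empty strata, isolated municipalities, and
  zero-variance surfaces all return defined values (0, full shrinkage, or
  the input unchanged) rather than NaN — each has a dedicated test.

# Limitations

* Circular windows only: elongated (coastline-following) true clusters are
  recovered as their closest circular approximation.
* No covariate adjustment beyond maternal age; no space–time scan; no
  fully Bayesian (BYM/CAR) smoothing — empirical Bayes only.
* Queen contiguity is vertex-based and assumes tessellated inputs; a
  shared edge whose endpoints differ between the two rings is missed.
* The Poisson truncation at `O ≤ n` biases simulated counts slightly
  downward at extreme rates; negligible below 10%.
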