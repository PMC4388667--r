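---
title: "Moment approximations and likelihood inference for E&R time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment approximations and likelihood inference for E&R time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfgp)
```

This vignette is the package's account of its model, its approximations,
and the design choices behind them: what is being computed, where the
knobs are, and what the validation studies do and do not establish.

## The experiment and its idealisation

An evolve-and-resequence (E&R) experiment founds a population of `N`
diploids by cloning `F` sequenced homozygous lines `2N/F` times each,
evolves it in discrete non-overlapping generations under random mating,
and pool-sequences it at generations `t_1 < ... < t_T`, usually in `R`
replicate populations started from the same founders. The observation at
site `j`, time `t_i`, replicate `k` is a read count
`D_ijk ~ Binomial(c_ijk, X_ijk)` with coverage `c_ijk` and latent
population frequency `X_ijk`. The exact likelihood would require summing
the many-locus Wright-Fisher transition kernel over all intermediate
population states, which is intractable, and diffusion asymptotics are
unreliable at the small `N` and short horizons typical of experiments on
flies or mice. The package instead treats `X` as a Gaussian process whose
mean and covariance are computed, conditional on the known founder
configuration, from one-, two- and three-locus Wright-Fisher models. The
approximation keeps the first two moments of the process — including
cross-time and cross-site covariances induced by drift and linkage — and
discards higher-order dependence.

## Neutral moments

For two linked neutral sites, one generation is deterministic
recombination `z -> z + r C eps` on the four haplotype frequencies
(`C = z1 z4 - z2 z3`, `eps = (-1, 1, 1, -1)`) followed by a multinomial
draw of `2N` gametes. Closed-form moments accurate to `O(r + 1/(2N))` are
implemented in `neutral_hap_means()`, `neutral_hap_second_moments()` and
`neutral_cross_moment()`, and marginalised to allele-frequency moments by
`neutral_allele_moments()`. Two remarks on these forms:

* The second-moment display was re-derived here by summing the
  one-generation moment recursion (driven by the LD-product moments
  `E(Z^i C_t)`) in closed form, and each term group is validated in the
  test suite against exhaustive enumeration of the chain for `2N = 4, 6`:
  the error is zero at `t = 1` and scales as the *square* of
  `r + 1/(2N)` thereafter, i.e. the forms are exact to their stated order.
* They are expansions in `t r` and `t/2N`. `check_tr()` warns when
  `t r >= 0.1`; and because the drift terms are linear in `t/(2N)`, the
  closed forms are not used where `t/(2N)` is large (see the effective
  population size estimator below).

## Selected moments: the delta recursion

With diploid selection (`1 : 1+hs : 1+s` at one locus) the transition map
becomes rational and no closed form exists. Writing `Z_t = Zbar_t + dZ_t`
about the deterministic path `Zbar_t = f(Zbar_{t-1})`, the engine
propagates `E(dZ)` and `E(dZ dZ')` one generation at a time through a
second-order Taylor expansion of the composed map (transition map followed
by the multinomial-sampling moments), and carries cross-time blocks
`E(dZ_t dZ_u')` forward with the Jacobian. This is `moment_recursion()`,
with `hap_transition()` as the map: marginal-fitness selection, then
recombination as a mixture over crossover patterns (no interference; for
three loci the two intervals recombine independently), then an explicit
simplex normalisation.

Numerical choices that matter:

* **Taylor order.** Second order, matching the structure of the recursion:
  each step needs only moments of total degree at most two from the
  previous step. At neutrality and one locus the recursion is exact; at
  `2N = 4` with `s = 0.5` its error against the exactly enumerated chain
  is several-fold smaller than the deterministic path's.
* **Derivatives.** The Jacobian and Hessians of the composed map are
  computed by exact algebraic differentiation (quotient rule for
  selection, constant Hessians for the quadratic recombination patterns,
  chain rule through the stages); a central finite-difference path
  (step 1e-6) exists solely to cross-validate it in the tests.
* **Simplex normalisation.** The recombination map is quadratic and
  homogeneous, so off-simplex rounding error in the disturbance moments
  would otherwise be amplified geometrically along the recursion (the
  radial direction has multiplier 2 per generation; over 50 generations
  that is catastrophic). A final normalisation stage `y -> y / sum(y)`,
  differentiated exactly, makes the composed map degree-0 homogeneous and
  removes the instability. Selection normalises implicitly, which is why
  the issue only surfaces in neutral models.
* **PSD repair.** The disturbance second-moment matrix is projected to the
  PSD cone (eigenvalue floor 1e-12) if a Cholesky check fails, with a
  warning; the assembled covariance is repaired the same way.

## Assembling the Gaussian approximation

`build_gp()` fills the (time x locus) mean vector and covariance matrix
for one replicate (replicates are iid, so one block serves all):

* selected locus: one-locus delta recursion;
* each neutral locus, when a selected locus is in the model: the marginal
  of the *two-locus* (selected + neutral) recursion — this shifts the
  neutral mean and variance for hitchhiking and provides the
  neutral-selected covariance from the same run;
* neutral-neutral pairs with a selected locus present: the marginal of the
  *three-locus* recursion containing both neutrals and the selected locus
  in genomic order (linked selection also distorts neutral-neutral
  covariances);
* all pairs in a fully neutral model: the closed-form neutral moments,
  with the exact one-locus drift variance on the diagonal.

Initial haplotype frequencies are tabulated directly from the founder
panel (`founder_init()`); the founder configuration is treated as known.
Means are clipped to `[1e-6, 1 - 1e-6]`. Within a likelihood-ratio fit the
null model is evaluated by the same engine assembly at `s = 0`, so the
null is exactly nested and `Lambda >= 0` holds structurally rather than up
to approximation mismatch.

## The likelihood and its boundary behaviour

With infinite coverage the likelihood is the Gaussian density at the
observed frequencies; with finite coverage the binomial emission is
approximated by Gaussian noise of variance `mu (1 - mu) / c` added to the
diagonal (`mu` the model mean), keeping the marginal closed-form. A
one-dimensional adaptive-quadrature evaluator of the exact
binomial-times-Gaussian integral (`gp_loglik_exact1()`) serves as the
oracle: the approximation is within 0.05 nats of it at the tested
operating points.

One genuine subtlety is absorption. When an allele is lost (or fixes), a
model with extreme `s` predicts the absorbed data with mean at the clip
boundary and variance collapsing to the floor — and an unbounded Gaussian
*density* then rewards that degenerate model without limit, pushing every
estimate at an absorbed site to the search boundary. The exact
Wright-Fisher model has no such divergence: an absorbed state predicts
absorbed data with probability one, and probabilities are bounded by one.
`gp_loglik()` therefore evaluates the joint density as a product of
one-dimensional conditionals (via the Cholesky factor, in fixed grid
order) and converts each conditional to a probability mass using the
resolution of the observation — `1/c` for read frequencies, `1/(2N)` for
exactly observed gamete frequencies — capped at one. For interior
trajectories the cap never binds and the value is the usual log-density
plus a constant; at absorbed trajectories it reproduces the exact model's
bounded behaviour. Zero-coverage observations are dropped.

## Estimators and tests

* `lr_scan()` maximises the likelihood over `s` in `[-0.5, 1]` by Brent
  search (tolerance 1e-4) per site and reports
  `Lambda = 2 (sup log L - log L(0))`, floored at zero; ranks break ties
  by genomic position. `empirical_null()` calibrates the max-over-sites
  statistic by neutral re-simulation (p-values `(1 + #{null >= obs}) /
  (n + 1)`); the asymptotic chi-square calibration is deliberately not the
  default at small `R`.
* `estimate_s()` is the same maximisation at a known site; with
  `model_loci = 5` four intermediate-frequency companion loci (evenly
  spread across the region, `choose_companions()`) join the fit, which
  mainly pays off at low coverage.
* `estimate_hs()` maximises over `(h, s)` with L-BFGS-B from four spread
  starts in the box `s` in `[1e-4, 1]`, `h` in `[-5, 50]` (the box and
  starts are this package's choice and the individually weakly-identified `h` and `s` are
  reported alongside their well-identified product `h s`).
* `estimate_ne()` profiles a neutral multi-locus likelihood over
  `log10 N_e` on a grid with golden-section refinement. It uses the delta
  recursion rather than the closed-form neutral moments: the grid reaches
  `N_e` small enough that `t/(2N)` is order one, where the linearised
  closed forms understate covariance decay and bias the estimate upward
  (about two-fold at `N = 100`, `t = 50` in our checks); the recursion
  tracks the decay geometrically. A flat-profile flag is raised when the
  top of the grid cannot be rejected (weak drift signal).
* `estimate_hotspot()` profiles the neutral likelihood over the hotspot
  multiplier `alpha` (`r_H = alpha r`) on a log grid, with the hotspot
  interval assumed known.
* `s_fix(T, F, x_f)` is the closed-form design aid: the SFS-weighted
  average selection coefficient needed to carry a founder allele to
  frequency `x_f` in `T` generations.

## The synthetic-data generator

`sim_founder_panel()` draws per-site derived-allele counts from the
neutral SFS (`P(k) ∝ 1/k`) and assigns carriers by block-copying: the
region is segmented into blocks of exponential length (mean `ld_scale_bp`)
and sites within a block draw nested carrier sets from one shared
permutation, giving strong short-range association (D' = 1 within blocks)
that decays with distance. Defaults are chosen once to emulate panels
sampled from a Drosophila-sized natural population: `theta_bp = 0.0035`
reproduces observed segregating-site densities per founder count
(about 1,230 / 2,060 / 2,860 sites per 100 kb at F = 20 / 200 / 2000),
and `ld_scale_bp = 12.5 = 1/(4 N r)` with `N = 1e6`, `r = 2e-8` per bp.
The forward simulator (`evolve_population()`, compiled) implements
fitness-proportional parent sampling and meiosis with crossovers as a
Poisson process whose per-interval intensity `-log(1 - 2 r_i)/2` gives
exactly the requested recombination fraction `min(r_bp * d, 0.5)` per
interval, independently across intervals (no interference). Pooled
sequencing draws Poisson or empirically resampled depths and binomial
counts. A deterministic (infinite-population) mode iterating the exact
haplotype map is provided for oracle tests.

What the generator does *not* emulate: mutation during the experiment,
overlapping generations, non-random mating, unequal replicates,
overdispersed (non-Poisson) coverage, sequencing error, or coalescent
gene genealogies beyond the block-copying caricature of LD. Passing tests
therefore show that the inference machinery is faithful to the idealised
Wright-Fisher experiment it models — not that real data meet those
idealisations.

## Study conditions and open choices

The validation studies (in `study_estimation_cell()` and friends, used by
the test suite and `scripts/acceptance.R`) follow the default design
`F = 200`, `N = 1000`, `t = {10, ..., 50}`, `R = 3`, with a fresh founder
panel per simulation; the estimation studies use a 20 kb region (small
enough that many replicate studies run on one CPU in minutes), while the
testing-power and localization studies use the full 100 kb region whose
segregating-site count sets the max-over-sites null distribution. Study
means and IQRs are compared at their own Monte-Carlo standard errors,
which scale correctly at any replication count.

Two conditions were genuinely open and decided here:

* **Starting frequency of the selected site.** For the estimation studies
  the selected site is conditioned on a starting minor-allele frequency of
  at least 0.1 (the same intermediate-frequency threshold used throughout
  for real-data filtering and companion selection). Without it, a
  substantial fraction of selected alleles start at `1/F` and are absorbed
  by drift, and the estimator's distribution is then dominated by
  absorption rather than by estimation error. The testing and
  localization studies use unconditioned random sites. The overdominance
  study excludes starts in `[0.4, 0.6]` only (trajectories beginning near
  the interior equilibrium are indistinguishable from drift).
* **Region nomination in the two-pass scan.** The original workflow
  nominated regions by visual inspection; `candidate_regions()` automates
  it as "windows strictly above the `(1 - q)` empirical quantile of the
  windowed mean statistic, merged when adjacent" with `q` configurable.
  This is a reproducible stand-in, not a calibrated detector.

## Known limitations

* Moments are truncated at second order; accuracy degrades as `t r`
  approaches 1, near absorption boundaries, and for very strong selection
  at very small `N` (the regimes are flagged or bounded as described).
* Trajectories absorbed at a boundary carry almost no information about
  the magnitude of selection beyond a threshold: with data saturated at
  fixation (or loss), every sufficiently strong (or strongly negative)
  `s` explains them essentially perfectly — in the exact Wright-Fisher
  model as well as in this approximation — so maximum-likelihood
  estimates from such trajectories sit near the search boundary. The
  starting-frequency conditioning reduces, but with sparse late sampling
  does not eliminate, this regime; estimates of `s` under designs that
  sample only late generations therefore have a heavier right tail than
  densely sampled designs.
* At most one selected locus per model, and at most three loci per
  moment model; larger fitted models (5 or 7 loci) are assembled pairwise,
  so their joint covariance is approximate beyond pairs and is PSD-repaired.
* The founder configuration is assumed known and exact; uncertainty in
  founder haplotypes is not propagated.
* Coverage is treated as fixed given the data; overdispersed sequencing
  noise beyond binomial-at-given-depth is not modelled.
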