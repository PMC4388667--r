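# wfgp

Likelihood-based inference for genomic time series from
evolve-and-resequence (E&R) experiments.

An E&R experiment founds a laboratory population from `F` sequenced inbred
lines, evolves it for tens of discrete generations at census size `N`
(typically with `R` replicate populations started from the same founders),
and pool-sequences it at generations `t_1 < ... < t_T`. The data are, for
every segregating site, derived-allele read counts `D_ijk ~ Binomial(c_ijk,
X_ijk)` where `c` is the coverage depth and `X` the latent population
allele frequency. **wfgp** is for researchers who want to detect, locate
and quantify selection in such data — or to power a planned experiment —
with a model that accounts jointly for genetic drift, linkage and
sequencing noise.

## The model

The latent frequency array is approximated by a Gaussian process,

```
X | G0, theta  ~  N( mu(G0, theta), Sigma(G0, theta) ),
```

conditional on the known founder haplotype configuration `G0`. The moment
functions are computed from small Wright-Fisher models rather than fitted:

* **Neutral sites.** For a pair of linked neutral sites the one-generation
  transition is `z -> z + r C eps` (haplotype frequencies `z`, linkage
  disequilibrium `C = z1 z4 - z2 z3`, `eps = (-1, 1, 1, -1)`) followed by
  multinomial resampling of `2N` gametes. Closed-form moments accurate to
  `O(r + 1/2N)` give every within- and cross-generation covariance.
* **Selected site.** With genotype fitnesses `1 : 1 + hs : 1 + s`, the
  frequency is decomposed as `X_t = Xbar_t + dX_t` about the deterministic
  selection trajectory, and the first two moments of the disturbance are
  propagated generation by generation through a second-order Taylor
  expansion of the (selection + recombination + multinomial sampling)
  transition — a delta-method moment recursion for one-, two- and
  three-locus models. Neutral sites linked to the selected site take their
  moments from the two- and three-locus recursions, which captures
  hitchhiking.

The likelihood of the read counts integrates the binomial emission over the
Gaussian state (a moment-matched Gaussian emission keeps it closed-form);
selection is tested per site with the likelihood-ratio statistic
`Lambda = -2 [ log L(s = 0) - sup_s log L(s) ]` against an empirical null
from neutral re-simulation, and `s`, `(h, s)`, the recombination rate of a
declared hotspot, and the effective population size `N_e` are estimated by
maximum likelihood. A two-pass genome scan (one-locus scan + windowing,
then 3/5/7-locus refits of candidate regions with distant neutral flanking
SNPs and a top-k intersection) handles chromosome-scale data.

The package also contains the full forward machinery to simulate E&R
experiments (founder panels with a neutral site-frequency spectrum and
distance-decaying LD, Wright-Fisher reproduction with diploid selection and
recombination in compiled code, Poisson/empirical pooled sequencing), which
powers its own validation studies.

## A worked example

```r
library(wfgp)

panel  <- sim_founder_panel(n_founders = 200, region_length = 20e3, seed = 1)
design <- er_design(n_diploid = 1000, generations = c(10, 20, 30, 40, 50),
                    n_replicates = 3, coverage = coverage_poisson(30))
set.seed(1)
site   <- sample_selected_site(panel, min_freq = 0.1)
ex     <- sim_er_experiment(panel, design, er_selection(site, s = 0.1), seed = 1)

scan <- lr_scan(ex$data, panel, design)
glance(scan)
localize_sites(scan, true_site = site)$rank_of_truth
estimate_s(ex$data, panel, design, site = site, model_loci = 5)
```

With seed 1 this prints (the panel has 411 segregating sites; the selected
site is site 180 at 9,359 bp, starting frequency 0.255):

```
# glance(scan)
  n_sites max_lambda top_site top_pos s_hat_top
1     411       133.      180    9359     0.112
# rank of the true site
[1] 1
# five-locus estimate at the known site
   site s_hat lambda loglik
1   180 0.111   134.  -185.
```

The scan's maximum likelihood-ratio statistic (133) lands on the true
selected site (rank 1), and the five-locus estimate of the selection
coefficient at that site is 0.111 for a true value of 0.10. `autoplot(scan)`
draws the per-site statistic along the region.

Designing an experiment instead: `s_fix(50, 200, 0.95)` returns 0.1118, the
SFS-averaged selection strength a new allele needs to reach frequency 0.95
within 50 generations given 200 founder lines — selection much weaker than
this cannot be expected to stand out from drift in such a design.

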