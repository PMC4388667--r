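test_that("the fixation design formula matches its closed form", {
  # F = 2: single term, H_1 = 1
  expect_equal(s_fix(50, 2, 0.9), log(0.9 / 0.1) / 50, tolerance = 1e-12)
  # doubling the duration halves the required selection
  expect_equal(s_fix(100, 200, 0.95), s_fix(50, 200, 0.95) / 2,
               tolerance = 1e-12)
  # the design value for the default experiment
  expect_equal(round(s_fix(50, 200, 0.95), 2), 0.11)
  expect_error(s_fix(50, 200, 1), "x_f")
})

test_that("noiseless trajectories recover the selection coefficient", {
  des <- er_design(n_diploid = 1000, n_replicates = 1)
  for (truth in c(0.05, 0.1)) {
    x <- 0.3
    tr <- numeric(50)
    for (t in 1:50) {
      x <- selection_step(x, truth, 0.5)
      tr[t] <- x
    }
    pan <- toy_panel(6, 20, positions = 500, region_length = 1000)
    data <- tibble::tibble(gen = des$generations, rep = 1L, site = 1L,
                           pos = 500, count = NA_integer_, coverage = Inf,
                           freq = tr[des$generations])
    est <- suppressWarnings(estimate_s(data, pan, des, site = 1))
    expect_lt(abs(est$s_hat - truth), 0.005)
  }
})

test_that("LR statistics are floored at zero and ranks are deterministic", {
  pan <- sim_founder_panel(20, 3000, n_sites = 6, seed = 17)
  des <- er_design(n_diploid = 300)
  ex <- sim_er_experiment(pan, des, seed = 3)
  sc <- suppressWarnings(lr_scan(ex$data, pan, des))
  expect_true(all(sc$lambda >= 0))
  expect_setequal(sc$rank, seq_len(nrow(sc)))
  # tie-breaking by ascending position
  tied <- tibble::tibble(site = c(2L, 1L), pos = c(200, 100),
                         lambda = c(5, 5))
  loc <- localize_sites(tied)
  expect_equal(loc$top$site, 1L)
  # single-site scan: trivially rank 1, distance 0
  one <- tibble::tibble(site = 9L, pos = 900, lambda = 3)
  l1 <- localize_sites(one, true_site = 9L)
  expect_equal(l1$rank_of_truth, 1L)
  expect_equal(l1$distance, 0)
})

test_that("empirical null is reproducible and p-values are valid", {
  pan <- sim_founder_panel(15, 1500, n_sites = 8, seed = 77)
  des <- er_design(n_diploid = 150, generations = c(10, 20),
                   n_replicates = 1)
  n1 <- suppressWarnings(empirical_null(pan, des, n_sims = 12, seed = 5))
  n2 <- suppressWarnings(empirical_null(pan, des, n_sims = 12, seed = 5))
  expect_identical(n1$lambda_max, n2$lambda_max)
  expect_true(all(n1$lambda_max >= 0))
  p <- null_pvalue(n1, c(0, 1e6, median(n1$lambda_max)))
  expect_true(all(p > 0 & p <= 1))
  expect_equal(p[2], 1 / 13)
})

test_that("null p-values of fresh neutral data are uniform (PIT)", {
  pan <- sim_founder_panel(15, 1500, n_sites = 8, seed = 78)
  des <- er_design(n_diploid = 150, generations = c(10, 20),
                   n_replicates = 1)
  null <- suppressWarnings(empirical_null(pan, des, n_sims = 19, seed = 6))
  pvals <- vapply(1:30, function(i) {
    ex <- sim_er_experiment(pan, des, seed = 5000 + i)
    sc <- suppressWarnings(lr_scan(ex$data, pan, des, tol = 1e-3))
    null_pvalue(null, max(sc$lambda))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ROC construction: identical and separated samples", {
  set.seed(4)
  a <- rexp(50)
  roc_same <- roc_points(a, a)
  expect_equal(roc_same$fpr, roc_same$tpr)
  roc_sep <- roc_points(a, a + 100)
  expect_equal(wfgp:::roc_tpr_at(roc_sep, 0), 1)
})

test_that("stronger selection separates better in a two-sample comparison", {
  # scaled-down ROC comparison: max-LR statistics under s = 0.1 versus
  # neutral on a small region
  pw <- study_power(12, s = 0.1, n_founders = 20, region_length = 3000,
                    n_diploid = 300, seed = 31)
  expect_gt(mean(pw$alt > quantile(pw$null, 0.75)), 0.5)
})

test_that("companion loci are intermediate-frequency and exclude the focal site", {
  pan <- sim_founder_panel(20, 20000, seed = 19)
  focal <- 10
  comp <- choose_companions(pan, focal, 4)
  expect_length(comp, 4)
  expect_false(focal %in% comp)
  f <- panel_freqs(pan)[comp]
  expect_true(all(f >= 0.1 & f <= 0.9))
  # spread on both sides of the focal position where possible
  expect_true(any(pan$positions[comp] < pan$positions[focal]) &&
                any(pan$positions[comp] > pan$positions[focal]))
})

test_that("joint (h, s) estimation recovers the product on clean trajectories", {
  des <- er_design(n_diploid = 1000, n_replicates = 3)
  pan <- toy_panel(4, 20, positions = 500, region_length = 1000)  # x0 = 0.2
  ex_data <- local({
    set.seed(61)
    ps <- subset_panel(pan, 1)
    ex <- sim_er_experiment(ps, des, er_selection(1, 0.01, 10), seed = 62)
    ex$data
  })
  est <- suppressWarnings(estimate_hs(ex_data, pan, des, site = 1))
  expect_gt(est$hs_hat, 0.04)
  expect_lt(est$hs_hat, 0.2)
})

test_that("effective-size estimation responds to the drift scale", {
  pan <- sim_founder_panel(20, 10000, n_sites = 40, seed = 91)
  des <- er_design(n_diploid = 100)
  x0 <- panel_freqs(pan)
  set.seed(92)
  sites <- sort(sample(which(x0 >= 0.2 & x0 <= 0.8), 5))
  ps <- subset_panel(pan, sites)
  ex <- sim_er_experiment(ps, des, seed = 93)
  est <- suppressWarnings(estimate_ne(ex$data, ps, des, sites = 1:5))
  expect_gt(est$ne_hat, 100 / 3)
  expect_lt(est$ne_hat, 100 * 3)
  # drift-scale identity: variances scale as 1/N_e, so a model whose
  # variances are doubled matches the data at twice the effective size
  est2 <- suppressWarnings(estimate_ne(ex$data, ps, des, sites = 1:5,
                                       sigma_scale = 2))
  expect_gt(est2$ne_hat, est$ne_hat * 1.4)
  expect_lt(est2$ne_hat, est$ne_hat * 3)
})

test_that("weak drift flattens the effective-size profile", {
  pan <- sim_founder_panel(20, 2000, n_sites = 4, seed = 95)
  des <- er_design(n_diploid = 50000, generations = 10, n_replicates = 1)
  ps <- subset_panel(pan, 1:3)
  ex <- sim_er_experiment(ps, des, seed = 96)
  est <- suppressWarnings(estimate_ne(ex$data, ps, des, sites = 1:3,
                                      log_range = c(2, 5), grid_n = 7))
  expect_true(est$flat)
})

test_that("within-hotspot covariance decreases with hotspot intensity", {
  # evaluate the neutral two-locus cross-covariance of a flanking pair on
  # an alpha grid at fixed t
  z <- c(0.4, 0.1, 0.1, 0.4)
  covs <- vapply(c(1, 10, 100, 1000), function(alpha) {
    m <- rec_map(1e-8, hotspot = list(start = 49000, end = 51000,
                                      alpha = alpha))
    r <- rec_fraction(48500, 51500, m)
    am <- suppressWarnings(
      neutral_allele_moments(two_locus_init(z, r, 1000), 30))
    am$cov[1, 2]
  }, numeric(1))
  expect_true(all(diff(covs) < 0))
})

test_that("hotspot intensity is recovered within an order of magnitude", {
  set.seed(71)
  pan <- sim_founder_panel(100, 1e5, n_sites = 500, seed = 71)
  hs <- list(start = 49000, end = 51000, alpha = 1000)
  des <- er_design(r_bp = 1e-8, hotspot = hs)
  x0 <- panel_freqs(pan)
  okf <- which(x0 >= 0.1 & x0 <= 0.9)
  ins <- intersect(which(pan$positions >= hs$start &
                           pan$positions <= hs$end), okf)
  ins <- head(ins, 6)
  outs <- sort(sample(setdiff(okf, ins), 14))
  ps <- subset_panel(pan, sort(c(ins, outs)))
  ex <- sim_er_experiment(ps, des, seed = 72)
  est <- suppressWarnings(
    estimate_hotspot(ex$data, ps, des, hotspot = hs,
                     sites = seq_along(ps$positions)))
  expect_lt(abs(log10(est$alpha_hat) - 3), 1)
  expect_error(
    estimate_hotspot(ex$data, ps, des,
                     hotspot = list(start = 1, end = 2, alpha = 1),
                     sites = seq_along(ps$positions)),
    "inside")
})
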