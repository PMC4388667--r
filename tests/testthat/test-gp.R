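test_that("recombination fractions accumulate linearly with hotspot additivity", {
  m <- rec_map(1e-8)
  expect_equal(rec_fraction(500, 500, m), 0)
  expect_equal(rec_fraction(1, 10001, m), 1e-4)
  mh <- rec_map(1e-8, hotspot = list(start = 49000, end = 51000,
                                     alpha = 1000))
  # interval spanning the whole 2 kb hotspot: background + (alpha-1)*r*2kb
  expect_equal(rec_fraction(40000, 60000, mh),
               20000 * 1e-8 + 2000 * 999 * 1e-8, tolerance = 1e-12)
  # capped at 1/2
  expect_equal(rec_fraction(1, 1e9, rec_map(1e-6)), 0.5)
})

test_that("founder tabulation recovers LD and marginal identities", {
  # perfect LD
  p <- founder_panel(rbind(c(1L, 1L), c(0L, 0L)), c(10, 20), 100)
  init <- founder_init(p, 1:2)
  pr <- init$pair(1, 2)
  expect_equal(pr$z, c(0.5, 0, 0, 0.5))
  expect_equal(pr$z[1] * pr$z[4] - pr$z[2] * pr$z[3], 0.25)

  # random panel: pairwise frequencies sum to 1, marginals consistent
  pan <- sim_founder_panel(40, 5000, n_sites = 12, seed = 8)
  init2 <- founder_init(pan, c(2, 5, 9))
  pr2 <- init2$pair(2, 9)
  expect_equal(sum(pr2$z), 1)
  expect_equal(pr2$z[1] + pr2$z[2], unname(panel_freqs(pan)[2]))
  expect_equal(pr2$z[1] + pr2$z[3], unname(panel_freqs(pan)[9]))
  tr <- init2$triple(2, 5, 9)
  expect_equal(sum(tr$z), 1)

  # large balanced panel with independent loci: c0 near 0
  set.seed(123)
  h <- cbind(rep(0:1, each = 100), rep(0:1, times = 100))
  h <- h[sample(200), ]
  h2 <- cbind(h[, 1], sample(h[, 2]))
  p3 <- founder_panel(h2, c(10, 20), 100)
  expect_lt(abs(panel_ld(p3, 1, 2)), 0.05)

  expect_error(founder_init(p, 1, selected = 2), "among")
})

test_that("neutral Gaussian assembly has martingale means and replicate additivity", {
  pan <- sim_founder_panel(20, 4000, n_sites = 6, seed = 14)
  des <- er_design(n_diploid = 300, n_replicates = 2)
  init <- founder_init(pan, c(1, 3, 5))
  th <- model_theta(ne = 300, map = rec_map(des$r_bp))
  gp <- build_gp(init, des, th)
  expect_equal(gp$mean, rep(unname(panel_freqs(pan)[c(1, 3, 5)]),
                            each = 5), tolerance = 1e-9)
  expect_equal(gp$sigma, t(gp$sigma))
  ev <- eigen(gp$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))

  # replicates are iid: two identical replicates double the log-likelihood
  x <- matrix(gp$mean + 0.01, 5, 3)
  fr <- array(c(x, x), c(5, 3, 2))
  cv <- array(Inf, c(5, 3, 2))
  ll2 <- gp_loglik(fr, cv, gp)
  ll1 <- gp_loglik(fr[, , 1, drop = FALSE], cv[, , 1, drop = FALSE], gp)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
})

test_that("log-likelihood at the mean equals the closed-form Gaussian value", {
  pan <- sim_founder_panel(20, 4000, n_sites = 6, seed = 14)
  des <- er_design(n_diploid = 300, n_replicates = 1)
  init <- founder_init(pan, c(1, 3))
  gp <- build_gp(init, des, model_theta(ne = 300, map = rec_map(des$r_bp)))
  fr <- array(gp$mean, c(5, 2, 1))
  cv <- array(Inf, c(5, 2, 1))
  n <- length(gp$mean)
  # density part, plus the 1/(2N) observation-resolution constant
  expected <- -0.5 * determinant(gp$sigma)$modulus[1] -
    0.5 * n * log(2 * pi) - n * log(2 * des$n_diploid)
  expect_equal(gp_loglik(fr, cv, gp), as.numeric(expected),
               tolerance = 1e-8)
  # inflating the covariance lowers the density at the mean
  gp2 <- gp; gp2$sigma <- gp$sigma * 4
  expect_lt(gp_loglik(fr, cv, gp2), gp_loglik(fr, cv, gp))
})

test_that("degenerate state reduces to the (Gaussianised) binomial emission", {
  gp <- structure(list(mean = 0.5, sigma = matrix(1e-14, 1, 1),
                       times = 1, loci = 1, positions = 100,
                       n_replicates = 1, ne = 1000, obs_n = 1000),
                  class = "er_gp")
  ll <- gp_loglik(array(0.5, c(1, 1, 1)), array(10, c(1, 1, 1)), gp)
  expect_lt(abs(ll - dbinom(5, 10, 0.5, log = TRUE)), 0.05)
})

test_that("Gaussian emission agrees with quadrature of the exact integral", {
  for (cse in list(c(d = 5, c = 10, mu = 0.5, v = 0.01),
                   c(d = 3, c = 12, mu = 0.3, v = 0.005),
                   c(d = 18, c = 30, mu = 0.55, v = 0.02))) {
    gp <- structure(list(mean = cse[["mu"]],
                         sigma = matrix(cse[["v"]], 1, 1),
                         times = 1, loci = 1, positions = 100,
                         n_replicates = 1, ne = 1000, obs_n = 1000),
                    class = "er_gp")
    ll <- gp_loglik(array(cse[["d"]] / cse[["c"]], c(1, 1, 1)),
                    array(cse[["c"]], c(1, 1, 1)), gp)
    llq <- gp_loglik_exact1(cse[["d"]], cse[["c"]], cse[["mu"]], cse[["v"]])
    expect_lt(abs(ll - llq), 0.05)
  }
})

test_that("likelihood is invariant to relabeling the alleles", {
  pan <- sim_founder_panel(20, 4000, n_sites = 10, seed = 23)
  des <- er_design(n_diploid = 400, coverage = coverage_poisson(20))
  sel <- 4
  ex <- sim_er_experiment(pan, des, er_selection(sel, 0.15, 0.7), seed = 9)
  arrs <- wfgp:::data_arrays(ex$data, pan, des)
  comp <- c(2, 7)
  ll <- wfgp:::prepare_fit(arrs, pan, des, sel, comp)

  # flipped experiment: complement panel, counts and frequencies
  pan_f <- founder_panel(1L - pan$haplotypes, pan$positions,
                         pan$region_length)
  data_f <- ex$data
  data_f$count <- data_f$coverage - data_f$count
  data_f$freq <- 1 - data_f$freq
  arrs_f <- wfgp:::data_arrays(data_f, pan_f, des)
  ll_f <- wfgp:::prepare_fit(arrs_f, pan_f, des, sel, comp)

  s <- 0.15; h <- 0.7
  s_f <- -s / (1 + s); h_f <- 1 - h
  expect_equal(suppressWarnings(ll(s, h)),
               suppressWarnings(ll_f(s_f, h_f)), tolerance = 1e-4)
})

test_that("on neutral data the neutral model beats a fixed selected model on average", {
  pan <- sim_founder_panel(20, 3000, n_sites = 5, seed = 31)
  des <- er_design(n_diploid = 300)
  site <- 3
  diffs <- vapply(1:20, function(i) {
    ex <- sim_er_experiment(pan, des, seed = 100 + i)
    arrs <- wfgp:::data_arrays(ex$data, pan, des)
    ll <- wfgp:::prepare_fit(arrs, pan, des, site)
    suppressWarnings(ll(0) - ll(0.1))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
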