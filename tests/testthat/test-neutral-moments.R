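test_that("haplotype means: no-recombination and linkage-equilibrium limits", {
  z <- c(0.4, 0.1, 0.2, 0.3)
  m0 <- neutral_hap_means(two_locus_init(z, 0, 1000), 10)
  expect_equal(m0$means, z)
  # c0 = 0: outer product of marginals
  zle <- as.numeric(outer(c(0.3, 0.7), c(0.6, 0.4)))  # (z1,z2,z3,z4)
  zle <- c(zle[1], zle[3], zle[2], zle[4])
  init <- two_locus_init(zle, 0.05, 1000)
  expect_equal(init$c0, 0, tolerance = 1e-12)
  expect_equal(suppressWarnings(neutral_hap_means(init, 20)$means), zle)
  # mass conservation holds exactly in the closed forms
  for (r in c(0.001, 0.05)) {
    mm <- suppressWarnings(
      neutral_hap_means(two_locus_init(z, r, 500), 15)$means)
    expect_equal(sum(mm), 1, tolerance = 1e-14)
  }
})

test_that("haplotype mean under LD decay matches the deterministic recursion", {
  z <- c(0.5, 0, 0, 0.5)
  init <- two_locus_init(z, 0.01, 1e6)
  got <- suppressWarnings(neutral_hap_means(init, 10)$means[1])
  # printed closed form
  expect_equal(got, 0.5 - 10 * 0.01 * 0.25 * (1 - 9 / 4e6), tolerance = 1e-12)
  # independent oracle: iterate z <- z + r C eps
  zz <- z
  for (t in 1:10) {
    C <- zz[1] * zz[4] - zz[2] * zz[3]
    zz <- zz + 0.01 * C * c(-1, 1, 1, -1)
  }
  expect_lt(abs(got - zz[1]), 2e-3)
  expect_equal(zz[1], 0.47609, tolerance = 1e-4)
})

test_that("second moments reduce to exact drift formulas at r = 0", {
  z <- c(0.4, 0.1, 0.2, 0.3)
  n <- 50; t <- 5
  p <- neutral_hap_second_moments(two_locus_init(z, 0, n), t)
  for (i in 1:4) {
    expect_equal(p[i, i], z[i]^2 + (t / (2 * n)) * z[i] * (1 - z[i]),
                 tolerance = 1e-12)
    for (j in setdiff(1:4, i)) {
      expect_equal(p[i, j], z[i] * z[j] * (1 - t / (2 * n)),
                   tolerance = 1e-12)
    }
  }
})

test_that("moments agree with exhaustive chain enumeration to O(r + 1/2N)", {
  ratios <- c()
  for (m in c(4, 6)) {
    z0 <- if (m == 4) c(2, 1, 1, 0) / 4 else c(2, 1, 2, 1) / 6
    for (r in c(0, 0.02, 0.05)) for (t in c(1, 3, 5)) {
      ex <- exact_two_locus(z0, r, m, t)
      init <- two_locus_init(z0, r, m / 2)
      am <- suppressWarnings(neutral_hap_means(init, t)$means)
      p <- suppressWarnings(neutral_hap_second_moments(init, t))
      err <- max(max(abs(ex$mean - am)), max(abs(ex$second - p)))
      bound <- r + 1 / m
      ratios <- rbind(ratios, c(m = m, t = t, ratio = err / bound))
      expect_lt(err, 1.0 * bound)
    }
  }
  # the error constant shrinks as N grows (second-order truncation)
  r4 <- max(ratios[ratios[, "m"] == 4, "ratio"])
  r6 <- max(ratios[ratios[, "m"] == 6, "ratio"])
  expect_lt(r6, r4)
})

test_that("second moments match Monte-Carlo two-locus simulation", {
  z0 <- c(0.25, 0.25, 0.25, 0.25)
  nrun <- 3e4
  set.seed(31)
  sn <- mc_two_locus(z0, 0.001, 500, at = 20, nrun = nrun)
  got <- neutral_hap_second_moments(two_locus_init(z0, 0.001, 500), 20)
  prod12 <- sn[[1]][, 1] * sn[[1]][, 2]
  expect_lt(abs(got[1, 2] - mean(prod12)), 3 * sd(prod12) / sqrt(nrun))
  prod11 <- sn[[1]][, 1]^2
  expect_lt(abs(got[1, 1] - mean(prod11)), 3 * sd(prod11) / sqrt(nrun))
})

test_that("cross-generation moments satisfy lag-zero and martingale identities", {
  z <- c(0.4, 0.1, 0.1, 0.4)
  init <- two_locus_init(z, 0.005, 1000)
  p <- suppressWarnings(neutral_hap_second_moments(init, 10))
  expect_equal(suppressWarnings(neutral_cross_moment(init, 10, 0)), p)
  # r = 0: E(Z_{t+u} Z_t) is the within-generation moment at t (tower)
  init0 <- two_locus_init(z, 0, 1000)
  expect_equal(neutral_cross_moment(init0, 10, 25),
               neutral_hap_second_moments(init0, 10))
})

test_that("marginal allele moments: LE independence and MC cross-covariance", {
  zle <- c(0.18, 0.42, 0.12, 0.28)   # c0 = 0
  init <- two_locus_init(zle, 0.01, 1000)
  am <- suppressWarnings(neutral_allele_moments(init, c(10, 20)))
  expect_equal(unname(am$means), c(0.6, 0.3))
  # cross-locus covariance vanishes to leading order at LE (residual terms
  # are within the O(r + 1/2N) approximation order)
  expect_lt(max(abs(am$cov[1:2, 3:4])), 1e-3)

  # maximal LD: positive covariance between the marginals, vs Monte Carlo
  z <- c(0.5, 0, 0, 0.5)
  init2 <- two_locus_init(z, 1e-4, 1000)
  am2 <- neutral_allele_moments(init2, 30)
  nrun <- 3e4
  set.seed(17)
  sn <- mc_two_locus(z, 1e-4, 1000, at = 30, nrun = nrun)
  xa <- rowSums(sn[[1]][, c(1, 2)]); xb <- rowSums(sn[[1]][, c(1, 3)])
  prod <- (xa - mean(xa)) * (xb - mean(xb))
  expect_gt(am2$cov[1, 2], 0)
  expect_lt(abs(am2$cov[1, 2] - cov(xa, xb)), 3 * sd(prod) / sqrt(nrun))
})

test_that("the t*r validity guard warns", {
  init <- two_locus_init(c(0.25, 0.25, 0.25, 0.25), 0.02, 1000)
  expect_warning(neutral_hap_means(init, 10), "t \\* r")
  expect_silent(neutral_hap_means(two_locus_init(
    c(0.25, 0.25, 0.25, 0.25), 1e-4, 1000), 10))
})
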