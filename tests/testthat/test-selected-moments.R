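test_that("one-locus selection map: boundaries, neutrality, exact value", {
  expect_equal(selection_step(0, 0.3, 0.7), 0)
  expect_equal(selection_step(1, 0.3, 0.7), 1)
  expect_equal(selection_step(0.37, 0, 0.5), 0.37)
  expect_equal(selection_step(0.5, 0.1, 0.5), 0.5375 / 1.05, tolerance = 1e-12)
  expect_error(selection_step(0.5, -1.5, 0.5), "fitness")
  # derivatives agree with numerical differentiation
  d <- wfgp:::selection_step_d(0.3, 0.2, 0.8)
  eps <- 1e-6
  f <- function(x) selection_step(x, 0.2, 0.8)
  expect_equal(d$f, f(0.3), tolerance = 1e-12)
  expect_equal(d$f1, (f(0.3 + eps) - f(0.3 - eps)) / (2 * eps),
               tolerance = 1e-6)
  expect_equal(d$f2, (f(0.3 + eps) - 2 * f(0.3) + f(0.3 - eps)) / eps^2,
               tolerance = 1e-3)
})

test_that("multi-locus transition: LE invariance, two-locus arithmetic, marginalisation", {
  # linkage equilibrium is invariant under recombination without selection
  xa <- 0.3; xb <- 0.7
  zle <- c(xa * xb, xa * (1 - xb), (1 - xa) * xb, (1 - xa) * (1 - xb))
  m2 <- wf_model(2, rec = 0.3, n_diploid = 100)
  expect_equal(hap_transition(zle, m2), zle, tolerance = 1e-12)

  # z -> z + r C eps with C = 0.25, r = 0.1
  m2b <- wf_model(2, rec = 0.1, n_diploid = 100)
  expect_equal(hap_transition(c(0.5, 0, 0, 0.5), m2b),
               c(0.475, 0.025, 0.025, 0.475), tolerance = 1e-12)

  # three loci at LE: selected-locus marginal equals the one-locus map
  marg <- c(0.4, 0.25, 0.6)
  z8 <- as.numeric(outer(outer(c(marg[1], 1 - marg[1]),
                               c(marg[2], 1 - marg[2])),
                         c(marg[3], 1 - marg[3])))
  # map from (a1,a2,a3) outer layout to hap_index order
  amat3 <- wfgp:::allele_matrix(3)
  z0 <- numeric(8)
  idx <- 1
  for (a3 in c(1, 0)) for (a2 in c(1, 0)) for (a1 in c(1, 0)) {
    z0[wfgp:::hap_index(matrix(c(a1, a2, a3), 1))] <-
      prod(ifelse(c(a1, a2, a3) == 1, marg, 1 - marg))
  }
  m3 <- wf_model(3, selected = 2, s = 0.1, h = 0.5, rec = c(0.01, 0.05),
                 n_diploid = 500)
  z1 <- hap_transition(z0, m3)
  expect_equal(as.numeric(amat3 %*% z1)[2],
               selection_step(marg[2], 0.1, 0.5), tolerance = 1e-10)
})

test_that("multinomial moments of degree <= 2", {
  expect_equal(multinomial_moment(1, 0, 1, 2, c(0.3, 0.7), 10), 0.3)
  expect_equal(multinomial_moment(2, 0, 1, 1, c(0.5, 0.5), 2), 0.3125)
  expect_equal(multinomial_moment(1, 1, 1, 2, c(0.5, 0.5), 5), 0.25 * 0.9)
  expect_error(multinomial_moment(2, 1, 1, 2, c(0.5, 0.5), 5), "degree")
})

test_that("analytic transition derivatives match finite differences", {
  set.seed(13)
  for (cfg in list(list(l = 1, sel = 1), list(l = 2, sel = 2),
                   list(l = 3, sel = 1), list(l = 3, sel = NA))) {
    mod <- wf_model(cfg$l, selected = cfg$sel, s = 0.25, h = 0.8,
                    rec = rep(0.07, cfg$l - 1), n_diploid = 100)
    z <- runif(2^cfg$l); z <- z / sum(z)
    da <- wfgp:::hap_transition_d(z, mod, "analytic")
    df <- wfgp:::hap_transition_d(z, mod, "fd")
    expect_equal(da$f, hap_transition(z, mod), tolerance = 1e-12)
    expect_lt(max(abs(da$jac - df$jac)), 1e-6)
    expect_lt(max(abs(da$hess - df$hess)), 1e-3)
    # mass conservation in the derivatives
    expect_equal(sum(da$f), 1, tolerance = 1e-12)
    expect_lt(max(abs(colSums(da$jac))), 1e-10)
  }
})

test_that("delta recursion is exact for the neutral one-locus model", {
  o <- wfgp:::one_locus_moments(0.3, 0, 0.5, 100, times = c(5, 20))
  vex <- 0.3 * 0.7 * (1 - (1 - 1 / 200)^c(5, 20))
  expect_equal(o$means, c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(diag(o$cov), vex, tolerance = 1e-12)
  # martingale: cov(X_5, X_20) = var(X_5), exactly
  expect_equal(o$cov[1, 2], vex[1], tolerance = 1e-14)
})

test_that("delta recursion beats the deterministic path against the exact chain", {
  ex <- exact_one_locus(0.5, 0.5, 0.5, n2 = 4, t = 3)
  o <- wfgp:::one_locus_moments(0.5, 0.5, 0.5, 2, times = 3)
  xd <- 0.5
  for (i in 1:3) xd <- selection_step(xd, 0.5, 0.5)
  expect_lt(abs(o$means - ex$mean), abs(xd - ex$mean))
  expect_lt(abs(o$means - ex$mean), 0.01)
  expect_lt(abs(o$cov[1, 1] - ex$var) / ex$var, 0.1)
})

test_that("engine and scalar one-locus paths are identical", {
  mod <- wf_model(1, selected = 1, s = 0.5, h = 0.5, n_diploid = 50)
  am <- allele_moments(moment_recursion(mod, c(0.5, 0.5), times = c(3, 10)))
  o <- wfgp:::one_locus_moments(0.5, 0.5, 0.5, 50, times = c(3, 10))
  expect_equal(am$means[, 1], o$means, tolerance = 1e-10)
  expect_equal(am$cov, o$cov, tolerance = 1e-10)
})

test_that("selected-site mean and variance match Monte-Carlo forward simulation", {
  nrun <- 3e4
  set.seed(41)
  mc <- mc_one_locus(0.1, 0.1, 0.5, N = 1000, at = 50, nrun = nrun)[, 1]
  o <- wfgp:::one_locus_moments(0.1, 0.1, 0.5, 1000, times = 50)
  expect_lt(abs(o$means - mean(mc)), 3 * sd(mc) / sqrt(nrun))
})

test_that("cross-time moments: lag zero, martingale, and MC covariance", {
  o <- wfgp:::one_locus_moments(0.3, 0.05, 0.5, 500, times = c(20, 40))
  # MC covariance between generations 20 and 40
  nrun <- 3e4
  set.seed(43)
  mc <- mc_one_locus(0.3, 0.05, 0.5, N = 500, at = c(20, 40), nrun = nrun)
  prod <- (mc[, 1] - mean(mc[, 1])) * (mc[, 2] - mean(mc[, 2]))
  expect_lt(abs(o$cov[1, 2] - cov(mc[, 1], mc[, 2])),
            3 * sd(prod) / sqrt(nrun))
  # s = 0 martingale through the matrix engine, and lag-0 accessor
  mod <- wf_model(1, n_diploid = 200)
  mom <- moment_recursion(mod, c(0.4, 0.6), times = c(10, 30))
  expect_equal(cross_time_moments(mom, 10, 0), mom$S[[1]])
  am <- allele_moments(mom)
  expect_equal(am$cov[1, 2], am$cov[1, 1], tolerance = 1e-12)
})

test_that("mass is conserved along the recursion", {
  set.seed(19)
  for (i in 1:3) {
    z0 <- runif(8); z0 <- z0 / sum(z0)
    mod <- wf_model(3, selected = sample(3, 1), s = runif(1, 0, 0.5),
                    h = runif(1, 0, 2), rec = runif(2, 0, 0.1),
                    n_diploid = 200)
    mom <- moment_recursion(mod, z0, times = c(10, 25))
    for (a in 1:2) {
      expect_equal(sum(mom$zbar[a + 1, ] + mom$mu[a, ]), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("selected-site mean is nondecreasing in s", {
  means <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(s) {
    wfgp:::one_locus_moments(0.2, s, 0.5, 1000, times = 30)$means
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("three-locus model: fixed selected locus reduces to neutral pair", {
  # selected locus (position 3 in sorted order) fixed for the derived allele
  z_pair <- c(0.3, 0.2, 0.1, 0.4)
  z8 <- numeric(8)
  for (a1 in c(1, 0)) for (a2 in c(1, 0)) {
    pair_idx <- wfgp:::hap_index(matrix(c(a1, a2), 1))
    z8[wfgp:::hap_index(matrix(c(a1, a2, 1), 1))] <- z_pair[pair_idx]
  }
  m3 <- wf_model(3, selected = 3, s = 0.3, h = 0.5, rec = c(0.01, 0.02),
                 n_diploid = 300)
  am3 <- allele_moments(moment_recursion(m3, z8, times = c(10, 20)))
  m2 <- wf_model(2, rec = 0.01, n_diploid = 300)
  am2 <- allele_moments(moment_recursion(m2, z_pair, times = c(10, 20)))
  expect_equal(am3$means[, 1:2], am2$means, tolerance = 1e-9)
  expect_equal(am3$cov[1:4, 1:4], am2$cov, tolerance = 1e-9)
})

test_that("hitchhiking lifts a neutral site in positive LD with selection", {
  # two loci in strong positive LD, selection on locus 1
  z <- c(0.25, 0.05, 0.05, 0.65)
  mod <- wf_model(2, selected = 1, s = 0.2, h = 0.5, rec = 0.001,
                  n_diploid = 1000)
  am <- allele_moments(moment_recursion(mod, z, times = c(10, 30)))
  x_neutral0 <- z[1] + z[3]
  expect_gt(am$means[1, 2], x_neutral0)
  expect_gt(am$means[2, 2], am$means[1, 2])
})

test_that("three-locus linked moments match the forward simulator", {
  # founder pool realising an 8-haplotype configuration; selection on the
  # middle locus
  set.seed(55)
  counts <- c(6, 8, 10)
  pan <- toy_panel(counts, 20, positions = c(100, 1100, 2100),
                   region_length = 2500)
  n <- 500
  pop <- clone_founders(pan, n)
  pop <- pop[sample(nrow(pop)), ]   # random union of gametes at t = 0
  z0 <- wfgp:::tabulate_haplotypes(pop)
  rr <- c(1e-3, 1e-3)
  des <- er_design(n_diploid = n, generations = 30, n_replicates = 1,
                   r_bp = 1e-6)
  nrun <- 4000
  xs <- matrix(NA_real_, nrun, 3)
  for (i in seq_len(nrun)) {
    xs[i, ] <- evolve_population(pop, pan$positions, des,
                                 er_selection(2, 0.1, 0.5))[1, ]
  }
  mod <- wf_model(3, selected = 2, s = 0.1, h = 0.5, rec = rr,
                  n_diploid = n)
  lm <- linked_neutral_moments(mod, z0, times = 30)
  for (j in 1:3) {
    expect_lt(abs(lm$means[1, j] - mean(xs[, j])),
              3 * sd(xs[, j]) / sqrt(nrun) + 2e-3)
  }
})
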