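#' One-generation diploid selection map for a single locus
#'
#' Exact genotype-frequency bookkeeping under random mating: with derived
#' homozygote fitness `1 + s` and heterozygote fitness `1 + h s`, the
#' derived-allele frequency after selection is
#' `x + s x (1-x) (h + (1-2h) x) / (1 + s x (2h + (1-2h) x))`.
#'
#' @param x derived-allele frequency in `[0, 1]` (vectorised).
#' @param s selection coefficient (`1 + s > 0`).
#' @param h dominance parameter (`1 + h s > 0`).
#' @return frequency after one generation of selection.
#' @export
#' @examples
#' selection_step(0.5, 0.1, 0.5)  # 0.5375 / 1.05 = 0.511905
selection_step <- function(x, s, h) {
  if (1 + s <= 0 || 1 + h * s <= 0) abort("invalid fitnesses")
  stopifnot(all(x >= 0 & x <= 1))
  x + s * x * (1 - x) * (h + (1 - 2 * h) * x) /
    (1 + s * x * (2 * h + (1 - 2 * h) * x))
}

# value, first and second derivative of the one-locus selection map
selection_step_d <- function(x, s, h) {
  # f(x) = x + g(x) / w(x) with g = s x (1-x) (h + (1-2h) x) and w the mean
  # fitness 1 + s x (2h + (1-2h) x); only the selection increment carries
  # the mean-fitness denominator
  a <- 1 - 2 * h
  g <- s * (h * x + (1 - 3 * h) * x^2 - a * x^3)
  g1 <- s * (h + 2 * (1 - 3 * h) * x - 3 * a * x^2)
  g2 <- s * (2 * (1 - 3 * h) - 6 * a * x)
  w <- 1 + s * (2 * h * x + a * x^2)
  w1 <- s * (2 * h + 2 * a * x)
  w2 <- 2 * s * a
  list(f = x + g / w,
       f1 = 1 + (g1 * w - g * w1) / w^2,
       f2 = g2 / w - 2 * g1 * w1 / w^2 - g * w2 / w^2 + 2 * g * w1^2 / w^3)
}

#' Specify a small multi-locus Wright-Fisher model
#'
#' Defines the one-generation transition of haplotype frequencies for
#' `L` loci (`L` in 1..3 for inference; up to 12 for the deterministic
#' simulator): diploid selection at one designated locus followed by
#' recombination between adjacent loci with given fractions and no
#' interference.
#'
#' @param n_loci number of loci `L`.
#' @param selected index (in 1..L) of the selected locus, or `NA`.
#' @param s,h selection parameters at the selected locus.
#' @param rec numeric vector of `L - 1` recombination fractions between
#'   adjacent loci, each in `[0, 0.5]`.
#' @param n_diploid diploid population size used for the sampling step.
#' @return object of class `wf_model`.
#' @export
wf_model <- function(n_loci, selected = NA, s = 0, h = 0.5,
                     rec = numeric(0), n_diploid = 1000) {
  if (length(rec) != n_loci - 1) abort("need n_loci - 1 recombination fractions")
  if (any(rec < 0 | rec > 0.5)) abort("recombination fractions must lie in [0, 0.5]")
  if (1 + s <= 0 || 1 + h * s <= 0) abort("invalid fitnesses")
  m <- 2^n_loci
  amat <- allele_matrix(n_loci)
  wmat <- NULL
  if (!is.na(selected) && s != 0) {
    g <- outer(amat[selected, ], amat[selected, ], "+")
    wmat <- matrix(1, m, m)
    wmat[g == 1] <- 1 + h * s
    wmat[g == 2] <- 1 + s
  }
  pats <- rec_patterns(n_loci, rec)
  # pattern Hessians are constant: precompute their stacked form
  # (column i = vec of the Hessian of component i of the recombination map)
  hr_stack <- matrix(0, m * m, m)
  for (p in pats) {
    for (i in seq_len(m)) {
      hr_stack[, i] <- hr_stack[, i] +
        p$c * as.numeric(outer(p$u[i, ], p$v[i, ]) +
                           outer(p$v[i, ], p$u[i, ]))
    }
  }
  structure(
    list(n_loci = n_loci, selected = selected, s = s, h = h, rec = rec,
         N = n_diploid, m = m, amat = amat, wmat = wmat,
         patterns = pats, hr_stack = hr_stack),
    class = "wf_model"
  )
}

# Recombination as a mixture over crossover patterns.  For each subset of
# the L-1 intervals, loci split into two blocks of parental origin and the
# offspring haplotype frequency is a product of the two block marginals:
#   z'_h = sum_p c_p (U_p z)_h (V_p z)_h
# with U_p, V_p 0/1 aggregation matrices.  Quadratic in z, so the pattern
# Hessians are constant.
rec_patterns <- function(l, rec) {
  m <- 2^l
  amat <- allele_matrix(l)
  n_int <- l - 1
  pats <- list()
  for (mask in 0:(2^max(n_int, 0) - 1)) {
    xo <- if (n_int > 0) as.logical(bitwAnd(mask, 2^(0:(n_int - 1)))) else logical(0)
    cp <- prod(ifelse(xo, rec, 1 - rec))
    if (cp == 0) next
    origin <- cumsum(c(0, xo)) %% 2            # 0/1 parental origin per locus
    lu <- which(origin == 0); lv <- which(origin == 1)
    u <- agg_matrix(amat, lu)
    v <- agg_matrix(amat, lv)
    pats[[length(pats) + 1]] <- list(c = cp, u = u, v = v)
  }
  pats
}

# m x m aggregation matrix: row h selects haplotypes matching h at loci `at`
agg_matrix <- function(amat, at) {
  m <- ncol(amat)
  if (length(at) == 0) return(matrix(1, m, m))
  a <- matrix(0, m, m)
  sub <- amat[at, , drop = FALSE]
  for (h in seq_len(m)) {
    a[h, ] <- as.numeric(colSums(sub == sub[, h]) == length(at))
  }
  a
}

#' One-generation haplotype transition map
#'
#' Applies diploid selection (haplotype weight = marginal fitness, with
#' fitness determined solely by the alleles at the selected locus) followed
#' by recombination to a haplotype-frequency vector.
#'
#' @param z haplotype frequency vector of length `2^L` on the simplex, in
#'   [hap_index()] order.
#' @param model a [wf_model()].
#' @return frequency vector after one generation (deterministic part).
#' @export
hap_transition <- function(z, model) {
  if (!is.null(model$wmat)) {
    w <- as.numeric(model$wmat %*% z)
    z <- z * w / sum(z * w)
  }
  out <- numeric(model$m)
  for (p in model$patterns) {
    out <- out + p$c * as.numeric(p$u %*% z) * as.numeric(p$v %*% z)
  }
  # explicit simplex normalisation: the quadratic recombination map is
  # homogeneous, so without it numerical off-simplex residue in the moment
  # recursion would be amplified geometrically
  out / sum(out)
}

# Transition map with exact Jacobian and Hessians.  Hessians are returned
# stacked as an m^2 x m matrix whose column i is vec(H_i); the moment
# recursion contracts them against vec(S) and composes them with single
# matrix products, which keeps the per-generation cost low.
hap_transition_d <- function(z, model, method = c("analytic", "fd")) {
  method <- match.arg(method)
  if (method == "fd") return(hap_transition_fd(z, model))
  m <- model$m
  i_cycle <- rep.int(seq_len(m), m)      # i2 index of vec position
  i_block <- rep(seq_len(m), each = m)   # i1 index of vec position
  if (!is.null(model$wmat)) {
    wm <- model$wmat
    w <- as.numeric(wm %*% z)
    wbar <- sum(z * w)
    zw <- z * w
    y <- zw / wbar
    js <- (diag(w, m) + z * wm) / wbar -
      outer(zw, 2 * w) / wbar^2
    # stacked Hessians of the selection stage, batched over components:
    # column i = vec of d^2 f_i; dni is the gradient of the numerator z_i w_i
    dmat <- diag(w, m) + t(wm * z)                 # column i = dni
    h3 <- matrix(0, m * m, m)
    for (i in seq_len(m)) {
      h3[(seq_len(m) - 1) * m + i, i] <- h3[(seq_len(m) - 1) * m + i, i] + wm[i, ]
      h3[(i - 1) * m + seq_len(m), i] <- h3[(i - 1) * m + seq_len(m), i] + wm[i, ]
    }
    w2 <- 2 * w
    hs_stack <- h3 / wbar -
      (dmat[i_cycle, ] * w2[i_block] + dmat[i_block, ] * w2[i_cycle]) / wbar^2 +
      outer(as.numeric(8 * outer(w, w) / wbar^3 - 2 * wm / wbar^2), zw)
  } else {
    y <- z
    js <- NULL
    hs_stack <- NULL
  }
  # recombination stage at y (constant stacked Hessians precomputed)
  f <- numeric(m)
  jr <- matrix(0, m, m)
  for (p in model$patterns) {
    uz <- as.numeric(p$u %*% y); vz <- as.numeric(p$v %*% y)
    f <- f + p$c * uz * vz
    jr <- jr + p$c * (vz * p$u + uz * p$v)
  }
  if (is.null(js)) {
    jac <- jr
    hess <- model$hr_stack
  } else {
    jac <- jr %*% js
    # vec(t(js) H_i js) per component, plus the chain-rule selection terms
    tj <- t(js)
    hess <- matrix(0, m * m, m)
    for (i in seq_len(m)) {
      hess[, i] <- tj %*% matrix(model$hr_stack[, i], m) %*% js
    }
    hess <- hess + hs_stack %*% t(jr)
  }
  # final normalisation stage n(y) = y / sum(y) with its chain rule (at a
  # simplex point sum(f) = 1): keeps the composed map degree-0 homogeneous
  # so the moment recursion cannot drift off the simplex
  sig <- sum(f)
  fn <- f / sig
  cs <- colSums(jac) / sig
  jn <- jac / sig - outer(fn, cs)
  mg <- t(jac) / sig                     # column i = gradient of f_i
  sum_h <- rowSums(hess)
  hess_n <- (hess - outer(sum_h, fn)) / sig -
    mg[i_cycle, ] * cs[i_block] - mg[i_block, ] * cs[i_cycle] +
    outer(as.numeric(outer(cs, cs)), 2 * fn)
  list(f = fn, jac = jn, hess = hess_n)
}

# central finite-difference derivatives (cross-validation path)
hap_transition_fd <- function(z, model, eps = 1e-6) {
  m <- model$m
  f0 <- hap_transition(z, model)
  jac <- matrix(0, m, m)
  for (j in seq_len(m)) {
    zp <- z; zp[j] <- zp[j] + eps
    zm <- z; zm[j] <- zm[j] - eps
    jac[, j] <- (hap_transition(zp, model) - hap_transition(zm, model)) / (2 * eps)
  }
  hess <- matrix(0, m * m, m)
  for (j in seq_len(m)) for (k in j:m) {
    zpp <- z; zpp[j] <- zpp[j] + eps; zpp[k] <- zpp[k] + eps
    zpm <- z; zpm[j] <- zpm[j] + eps; zpm[k] <- zpm[k] - eps
    zmp <- z; zmp[j] <- zmp[j] - eps; zmp[k] <- zmp[k] + eps
    zmm <- z; zmm[j] <- zmm[j] - eps; zmm[k] <- zmm[k] - eps
    d2 <- (hap_transition(zpp, model) - hap_transition(zpm, model) -
           hap_transition(zmp, model) + hap_transition(zmm, model)) /
      (4 * eps^2)
    hess[(k - 1) * m + j, ] <- d2
    hess[(j - 1) * m + k, ] <- d2
  }
  list(f = f0, jac = jac, hess = hess)
}

#' Low-order multinomial moments
#'
#' Expected value of `Z_i^u Z_j^v` (total degree at most 2) when `2N Z` is
#' multinomially distributed with `2N` trials and success probabilities `p`;
#' obtained from the multinomial moment generating function.
#'
#' @param u,v non-negative integer exponents with `u + v <= 2`.
#' @param i,j category indices.
#' @param p success probabilities on the simplex.
#' @param n_diploid diploid size `N` (the multinomial has `2N` trials).
#' @return the requested moment.
#' @export
#' @examples
#' multinomial_moment(2, 0, 1, 1, c(0.5, 0.5), n_diploid = 2)  # 0.3125
multinomial_moment <- function(u, v, i, j, p, n_diploid) {
  if (u + v > 2) abort("only moments of total degree <= 2 are supported")
  n2 <- 2 * n_diploid
  if (u + v == 0) return(1)
  if (u + v == 1) {
    k <- if (u == 1) i else j
    return(p[k])
  }
  if (u == 2 || v == 2) {
    k <- if (u == 2) i else j
    return(p[k]^2 + p[k] * (1 - p[k]) / n2)
  }
  if (i == j) return(p[i]^2 + p[i] * (1 - p[i]) / n2)
  p[i] * p[j] * (1 - 1 / n2)
}

#' Delta-method moment recursion about the deterministic path
#'
#' Decomposes `Z_t = Zbar_t + dZ_t`, where `Zbar` follows the deterministic
#' transition map, and propagates the first and second moments of the
#' disturbance `dZ` one generation at a time through a second-order Taylor
#' expansion of the composed map (multinomial-sampling moments of the
#' transition) about `Zbar`.  Cross-generation second moments between each
#' pair of sampling times are carried forward with the Jacobian of the map.
#'
#' @param model a [wf_model()].
#' @param z0 initial haplotype frequencies (length `2^L`), known exactly
#'   (so the disturbance moments start at zero).
#' @param times strictly increasing positive sampling generations.
#' @param deriv `"analytic"` for exact algebraic derivatives of the
#'   transition map (default) or `"fd"` for central finite differences.
#' @return object of class `wf_moments`: list with
#'   \describe{
#'     \item{zbar}{`(T+1) x m` deterministic path at `c(0, times)`.}
#'     \item{mu}{`T x m` disturbance means at the sampling times.}
#'     \item{S}{list of `m x m` matrices `E(dZ dZ')` per sampling time.}
#'     \item{cross}{`T x T` list-matrix; `cross[[a]][[b]]`, `a >= b`, holds
#'       `E(dZ_{t_a} dZ_{t_b}')`.}
#'     \item{model, times}{inputs.}
#'   }
#' @export
moment_recursion <- function(model, z0, times, deriv = "analytic") {
  m <- model$m
  n2 <- 2 * model$N
  stopifnot(length(z0) == m, abs(sum(z0) - 1) < 1e-8)
  times <- as.integer(times)
  tt <- length(times)
  zbar <- z0
  mu <- rep(0, m)
  s <- matrix(0, m, m)
  snap_z <- matrix(NA_real_, tt + 1, m); snap_z[1, ] <- z0
  snap_mu <- matrix(NA_real_, tt, m)
  snap_s <- vector("list", tt)
  cross <- vector("list", tt)
  live <- list()   # cross blocks E(dZ_now dZ_{t_b}') for stored times b
  ti <- 1L
  psd_warned <- FALSE
  for (t in seq_len(max(times))) {
    d <- hap_transition_d(zbar, model, method = deriv)
    y <- d$f; jac <- d$jac
    tr_h <- as.numeric(crossprod(d$hess, as.numeric(s)))
    u <- as.numeric(jac %*% mu)
    ez <- y + u + tr_h / 2                     # E Z_{t}
    # E f f' to second order
    eff <- outer(y, y) + outer(y, u) + outer(u, y) +
      (outer(y, tr_h) + outer(tr_h, y)) / 2 +
      jac %*% s %*% t(jac)
    e2 <- (1 - 1 / n2) * eff + diag(ez, m) / n2
    s_new <- e2 - outer(y, ez) - outer(ez, y) + outer(y, y)
    s_new <- (s_new + t(s_new)) / 2
    ok <- !inherits(tryCatch(chol(s_new + 1e-12 * diag(m)),
                             error = function(e) e), "error")
    if (!ok) {
      if (!psd_warned) {
        warn("disturbance second-moment matrix lost positive semidefiniteness; projecting")
        psd_warned <- TRUE
      }
      s_new <- psd_repair(s_new)
    }
    mu <- ez - y
    s <- s_new
    zbar <- y
    live <- lapply(live, function(cb) jac %*% cb)
    if (ti <= tt && t == times[ti]) {
      snap_z[ti + 1, ] <- zbar
      snap_mu[ti, ] <- mu
      snap_s[[ti]] <- s
      cross[[ti]] <- c(live, list(s))
      live <- c(live, list(s))
      ti <- ti + 1L
    }
  }
  structure(
    list(zbar = snap_z, mu = snap_mu, S = snap_s, cross = cross,
         model = model, times = times),
    class = "wf_moments"
  )
}

#' Allele-frequency moments from a haplotype moment recursion
#'
#' Marginalises a [moment_recursion()] result to the `L` derived-allele
#' frequencies: means `E X_t`, and the full covariance over the
#' (time x locus) grid including cross-time blocks.
#'
#' @param mom a `wf_moments` object.
#' @return list with `means` (`T x L`) and `cov` (`TL x TL`, index
#'   `(locus - 1) * T + time`).
#' @export
allele_moments <- function(mom) {
  amat <- mom$model$amat
  l <- nrow(amat); tt <- length(mom$times)
  means <- matrix(NA_real_, tt, l)
  cv <- matrix(0, l * tt, l * tt)
  for (a in seq_len(tt)) {
    means[a, ] <- as.numeric(amat %*% (mom$zbar[a + 1, ] + mom$mu[a, ]))
    for (b in seq_len(a)) {
      blk <- mom$cross[[a]][[b]] - outer(mom$mu[a, ], mom$mu[b, ])
      xblk <- amat %*% blk %*% t(amat)       # l x l, rows = time a
      for (la in seq_len(l)) for (lb in seq_len(l)) {
        cv[(la - 1) * tt + a, (lb - 1) * tt + b] <- xblk[la, lb]
        cv[(lb - 1) * tt + b, (la - 1) * tt + a] <- xblk[la, lb]
      }
    }
  }
  list(means = means, cov = cv, times = mom$times)
}

#' Cross-time disturbance moments
#'
#' Convenience accessor for `E(dZ_{t+u}^i dZ_t^j)` from a fitted moment
#' recursion (both `t` and `t + u` must be sampling times of the recursion).
#'
#' @param mom a `wf_moments` object.
#' @param t,u base time and lag.
#' @return `m x m` matrix with rows indexing time `t + u`.
#' @export
cross_time_moments <- function(mom, t, u) {
  a <- match(t + u, mom$times)
  b <- match(t, mom$times)
  if (is.na(a) || is.na(b)) abort("t and t+u must be sampling times of the recursion")
  mom$cross[[a]][[b]]
}

# ---- scalar fast path for the one-locus selected model ------------------

# One-locus delta recursion; returns means, variances and the full T x T
# covariance (cross-time via Jacobian products).  Used by the per-site
# likelihood where speed matters; agrees with moment_recursion() on the
# 2-haplotype model (cross-validated in the tests).
one_locus_moments <- function(x0, s, h, n_diploid, times) {
  n2 <- 2 * n_diploid
  tt <- length(times)
  xbar <- x0; mu <- 0; s2 <- 0                 # s2 = E(dX^2)
  snap_mean <- numeric(tt)
  mu_store <- numeric(tt)
  live <- numeric(0)                           # E(dX_now dX_{t_b})
  cv <- matrix(0, tt, tt)
  ti <- 1L
  neutral <- (s == 0)
  for (t in seq_len(max(times))) {
    if (neutral) {
      f <- xbar; f1 <- 1; f2 <- 0
    } else {
      d <- selection_step_d(xbar, s, h)
      f <- d$f; f1 <- d$f1; f2 <- d$f2
    }
    ex <- f + f1 * mu + f2 * s2 / 2
    ef2 <- f^2 + 2 * f * f1 * mu + (f1^2 + f * f2) * s2
    ex2 <- (1 - 1 / n2) * ef2 + ex / n2
    s2 <- max(ex2 - f^2 - 2 * f * (ex - f), 0)
    mu <- ex - f
    xbar <- f
    if (length(live)) live <- f1 * live
    if (ti <= tt && t == times[ti]) {
      snap_mean[ti] <- xbar + mu
      mu_store[ti] <- mu
      live <- c(live, s2)
      for (b in seq_len(ti)) {
        cv[ti, b] <- cv[b, ti] <- live[b] - mu * mu_store[b]
      }
      ti <- ti + 1L
    }
  }
  list(means = snap_mean, cov = cv, times = times)
}

#' Neutral-site moments conditioned on a linked selected site
#'
#' Runs the delta-method recursion on the 8-haplotype (three-locus) model
#' containing two neutral sites and one selected site, and marginalises to
#' allele-frequency moments.  A neutral site in positive LD with a
#' positively selected allele is dragged upward in frequency (hitchhiking),
#' which a one-locus neutral model would miss.
#'
#' @param model a three-locus [wf_model()] with a selected locus.
#' @param z0 initial 8-haplotype frequencies (e.g. tabulated from a founder
#'   panel).
#' @param times sampling generations.
#' @return as [allele_moments()]: means `T x 3` and covariance over the
#'   (time x locus) grid.
#' @export
linked_neutral_moments <- function(model, z0, times) {
  if (model$n_loci != 3) abort("linked_neutral_moments expects a three-locus model")
  allele_moments(moment_recursion(model, z0, times))
}
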