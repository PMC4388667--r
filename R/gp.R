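#' Recombination maps and fractions
#'
#' A recombination map is a background per-basepair rate plus an optional
#' hotspot interval with an elevated rate `alpha * r_bp`.  The fraction
#' between two positions is the rate integrated over the spanned interval,
#' capped at 1/2.
#'
#' @param r_bp background recombination rate per basepair per generation.
#' @param hotspot optional list with `start`, `end` (bp) and `alpha`.
#' @return an object of class `rec_map`.
#' @export
rec_map <- function(r_bp, hotspot = NULL) {
  structure(list(r_bp = r_bp, hotspot = hotspot), class = "rec_map")
}

#' @rdname rec_map
#' @param pos_a,pos_b basepair positions.
#' @param map a `rec_map`.
#' @export
#' @examples
#' rec_fraction(1, 10001, rec_map(1e-8))  # 1e-4
rec_fraction <- function(pos_a, pos_b, map) {
  lo <- pmin(pos_a, pos_b); hi <- pmax(pos_a, pos_b)
  d <- hi - lo
  frac <- d * map$r_bp
  hs <- map$hotspot
  if (!is.null(hs)) {
    ov <- pmax(0, pmin(hi, hs$end) - pmax(lo, hs$start))
    frac <- frac + ov * (hs$alpha - 1) * map$r_bp
  }
  pmin(frac, 0.5)
}

#' Tabulate the initial state from a founder panel
#'
#' Computes, directly from the founder haplotype matrix, the empirical
#' marginal frequencies of the requested loci, the pairwise two-locus
#' haplotype frequencies and LD, and (when a selected locus is given) the
#' three-locus haplotype frequencies of each neutral pair with the selected
#' locus.  The founding configuration is assumed known, so these frequencies
#' enter the Gaussian approximation without uncertainty.
#'
#' @param panel a [founder_panel()].
#' @param loci integer vector of panel site indices to model.
#' @param selected optional panel site index of the selected locus (must be
#'   an element of `loci`).
#' @return object of class `founder_init`: list with `loci`, `positions`,
#'   `x0`, `selected`, and accessors `pair(a, b)` / `triple(a, b)` returning
#'   haplotype frequency vectors in [hap_index()] order for loci sorted by
#'   genomic position.
#' @export
founder_init <- function(panel, loci, selected = NA) {
  loci <- as.integer(loci)
  x0 <- colMeans(panel$haplotypes[, loci, drop = FALSE])
  if (any(x0 <= 0 | x0 >= 1)) abort("monomorphic locus requested")
  if (!is.na(selected) && !(selected %in% loci)) {
    abort("selected locus must be among the modelled loci")
  }
  haps <- panel$haplotypes
  tab <- function(cols) {
    cols <- sort(cols)
    z <- tabulate(hap_index(haps[, cols, drop = FALSE]),
                  nbins = 2^length(cols)) / nrow(haps)
    list(z = z, cols = cols)
  }
  structure(
    list(loci = loci, positions = panel$positions[loci], x0 = x0,
         selected = if (is.na(selected)) NA_integer_ else as.integer(selected),
         pair = function(a, b) tab(c(a, b)),
         triple = function(a, b, c) tab(c(a, b, c))),
    class = "founder_init"
  )
}

#' Pairwise LD between two panel sites
#' @param panel a [founder_panel()].
#' @param a,b site indices.
#' @return the LD coefficient `C = z1 z4 - z2 z3`.
#' @export
panel_ld <- function(panel, a, b) {
  z <- tabulate(hap_index(panel$haplotypes[, c(a, b), drop = FALSE]),
                nbins = 4) / nrow(panel$haplotypes)
  z[1] * z[4] - z[2] * z[3]
}

#' Model parameters for the Gaussian approximation
#'
#' @param s,h selection parameters at the selected locus (`s = 0` for the
#'   neutral model).
#' @param selected panel site index of the selected locus, or `NA`.
#' @param ne effective diploid population size.
#' @param map a [rec_map()].
#' @return object of class `model_theta`.
#' @export
model_theta <- function(s = 0, h = 0.5, selected = NA, ne, map) {
  if (ne < 1) abort("ne must be >= 1")
  if (1 + s <= 0 || 1 + h * s <= 0) abort("invalid fitnesses")
  structure(list(s = s, h = h,
                 selected = if (is.na(selected)) NA_integer_ else as.integer(selected),
                 ne = ne, map = map),
            class = "model_theta")
}

# mean clipping bounds for the Gaussian approximation
.mean_clip <- c(1e-6, 1 - 1e-6)

#' Assemble the Gaussian approximation over the sampling grid
#'
#' Builds the mean vector and covariance matrix of the latent
#' allele-frequency array over the (time x locus) grid for one replicate;
#' replicates are independent and identically distributed, so the same block
#' applies to each.  Moment sources:
#' \itemize{
#'   \item selected locus with itself: one-locus delta recursion;
#'   \item neutral locus (selection in the model): marginal of the two-locus
#'     delta recursion containing the selected locus, which also provides
#'     the neutral-selected covariance;
#'   \item two neutral loci with a selected locus present: marginal of the
#'     three-locus delta recursion (neutral pair plus selected locus,
#'     ordered by genomic position);
#'   \item all pairs under the neutral model: closed-form neutral two-locus
#'     moments, with the exact one-locus drift variance on the diagonal.
#' }
#' Means are clipped to `[1e-6, 1 - 1e-6]` and the covariance is projected
#' to the PSD cone (eigenvalue floor 1e-12) after assembly.
#'
#' @param init a [founder_init()].
#' @param design an [er_design()].
#' @param theta a [model_theta()].
#' @param engine_null use the delta-recursion engine for the neutral model
#'   too (`TRUE` inside likelihood-ratio fits so that the null is nested in
#'   the alternative; `FALSE` uses the closed-form neutral moments).
#' @return object of class `er_gp` with `mean` (length `T K`), `sigma`
#'   (`TK x TK`, index `(locus - 1) * T + time`), `times`, `positions`,
#'   `n_replicates`.
#' @export
build_gp <- function(init, design, theta, engine_null = FALSE) {
  tvec <- design$generations
  tt <- length(tvec)
  loci <- init$loci
  k <- length(loci)
  ne <- theta$ne
  # the engine path is keyed on a *designated* selected locus (even at
  # s = 0) so that the null model of a likelihood-ratio fit is evaluated
  # with exactly the same model structure as the alternative
  has_sel <- !is.na(theta$selected)
  use_engine <- has_sel || engine_null
  mean_v <- numeric(tt * k)
  sigma <- matrix(0, tt * k, tt * k)
  ix <- function(j) (j - 1) * tt + seq_len(tt)
  rfrac <- function(a, b) rec_fraction(init$positions[match(a, loci)],
                                       init$positions[match(b, loci)],
                                       theta$map)
  sel <- theta$selected

  if (!use_engine) {
    # closed-form neutral assembly
    for (j in seq_len(k)) {
      x <- init$x0[j]
      mean_v[ix(j)] <- x
      vmin <- x * (1 - x) * (1 - (1 - 1 / (2 * ne))^tvec)
      sigma[ix(j), ix(j)] <- outer(seq_len(tt), seq_len(tt),
                                   function(a, b) vmin[pmin(a, b)])
    }
    if (k > 1) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        pr <- init$pair(loci[a], loci[b])
        i2 <- two_locus_init(pr$z, rfrac(loci[a], loci[b]), ne)
        am <- suppressWarnings(neutral_allele_moments(i2, tvec))
        # pr$cols sorted = (loci[a], loci[b]) since loci indices follow position
        sigma[ix(a), ix(b)] <- am$cov[seq_len(tt), tt + seq_len(tt)]
        sigma[ix(b), ix(a)] <- t(sigma[ix(a), ix(b)])
      }
    }
  } else {
    sj <- if (has_sel) match(sel, loci) else NA_integer_
    if (!is.na(sj)) {
      # selected locus: one-locus selected recursion for its own block
      o <- one_locus_moments(init$x0[sj], theta$s, theta$h, ne, tvec)
      mean_v[ix(sj)] <- o$means
      sigma[ix(sj), ix(sj)] <- o$cov
      # each neutral locus: marginal of the two-locus (selected, neutral)
      # recursion, which captures the hitchhiking shift of its mean and
      # variance and yields the neutral-selected covariance consistently
      for (j in setdiff(seq_len(k), sj)) {
        pr <- init$pair(loci[j], sel)
        mod <- wf_model(2, selected = match(sel, pr$cols), s = theta$s,
                        h = theta$h, rec = rfrac(loci[j], sel),
                        n_diploid = ne)
        am <- allele_moments(moment_recursion(mod, pr$z, tvec))
        lj <- match(loci[j], pr$cols); ls <- match(sel, pr$cols)
        jb <- (lj - 1) * tt + seq_len(tt)
        sb <- (ls - 1) * tt + seq_len(tt)
        mean_v[ix(j)] <- am$means[, lj]
        sigma[ix(j), ix(j)] <- am$cov[jb, jb]
        sigma[ix(j), ix(sj)] <- am$cov[jb, sb]
        sigma[ix(sj), ix(j)] <- am$cov[sb, jb]
      }
      # neutral-neutral pairs: marginal of the three-locus model that also
      # carries the selected locus (genomic order)
      neut <- setdiff(seq_len(k), sj)
      if (length(neut) > 1) {
        for (ai in seq_len(length(neut) - 1)) {
          for (bi in (ai + 1):length(neut)) {
            a <- neut[ai]; b <- neut[bi]
            tr <- init$triple(loci[a], loci[b], sel)
            cols <- tr$cols
            rr <- c(rfrac(cols[1], cols[2]), rfrac(cols[2], cols[3]))
            mod <- wf_model(3, selected = match(sel, cols), s = theta$s,
                            h = theta$h, rec = rr, n_diploid = ne)
            am <- allele_moments(moment_recursion(mod, tr$z, tvec))
            la <- match(loci[a], cols); lb <- match(loci[b], cols)
            blk <- am$cov[(la - 1) * tt + seq_len(tt),
                          (lb - 1) * tt + seq_len(tt)]
            sigma[ix(a), ix(b)] <- blk
            sigma[ix(b), ix(a)] <- t(blk)
          }
        }
      }
    } else {
      # engine-based neutral assembly (no designated locus)
      for (j in seq_len(k)) {
        o <- one_locus_moments(init$x0[j], 0, theta$h, ne, tvec)
        mean_v[ix(j)] <- o$means
        sigma[ix(j), ix(j)] <- o$cov
      }
      if (k > 1) {
        for (a in seq_len(k - 1)) for (b in (a + 1):k) {
          pr <- init$pair(loci[a], loci[b])
          mod <- wf_model(2, rec = rfrac(loci[a], loci[b]), n_diploid = ne)
          am <- allele_moments(moment_recursion(mod, pr$z, tvec))
          la <- match(loci[a], pr$cols); lb <- match(loci[b], pr$cols)
          blk <- am$cov[(la - 1) * tt + seq_len(tt),
                        (lb - 1) * tt + seq_len(tt)]
          sigma[ix(a), ix(b)] <- blk
          sigma[ix(b), ix(a)] <- t(blk)
        }
      }
    }
  }
  mean_v <- pmin(pmax(mean_v, .mean_clip[1]), .mean_clip[2])
  sigma <- psd_repair(sigma)
  structure(
    list(mean = mean_v, sigma = sigma, times = tvec,
         loci = loci, positions = init$positions,
         n_replicates = design$n_replicates, ne = ne,
         obs_n = design$n_diploid),
    class = "er_gp"
  )
}

#' Gaussian-process log-likelihood of pool-seq trajectories
#'
#' With infinite coverage the likelihood is the multivariate Gaussian
#' density at the observed frequencies.  With finite coverage the binomial
#' sequencing emission is approximated by a Gaussian: the observed frequency
#' `d/c` is treated as the latent frequency plus noise of variance
#' `mu (1 - mu) / c` (with `mu` the model mean), which adds to the diagonal
#' of the covariance and keeps the marginal likelihood closed-form.
#'
#' The joint density is evaluated as a product of one-dimensional
#' conditionals (via the Cholesky factorisation, in the fixed locus-major
#' grid order), and each conditional is converted to a probability mass by
#' multiplying with the resolution of the observation (`1/c` reads at
#' finite coverage; `1/(2N)` gamete frequencies at infinite coverage) and
#' capping at one.  The cap is inactive for interior trajectories, where the
#' value agrees with the quadrature oracle [gp_loglik_exact1()] up to the
#' emission approximation, but it bounds the likelihood when a trajectory is
#' absorbed at 0 or 1: a degenerate model state that predicts the absorbed
#' data exactly then contributes probability one (as in the exact
#' Wright-Fisher model) rather than an unbounded density.  Observations with
#' zero coverage carry no information and are dropped.  Replicates are
#' independent, so the log-likelihood is a sum over identical replicate
#' blocks.
#'
#' @param freq numeric array `T x K x R` of observed frequencies (`d/c`, or
#'   the exact frequencies when coverage is infinite); `NaN`/`NA` entries
#'   are dropped.
#' @param coverage array of the same shape (`Inf` for exact observation).
#' @param gp an [build_gp()] result.
#' @return log-likelihood value.
#' @export
gp_loglik <- function(freq, coverage, gp) {
  tt <- length(gp$times); k <- length(gp$loci)
  if (length(dim(freq)) == 2) dim(freq) <- c(dim(freq), 1)
  if (is.null(dim(coverage)) || length(dim(coverage)) == 2) {
    coverage <- array(coverage, dim(freq))
  }
  stopifnot(dim(freq)[1] == tt, dim(freq)[2] == k)
  ll <- 0
  for (r in seq_len(dim(freq)[3])) {
    x <- as.numeric(freq[, , r])
    cv <- as.numeric(coverage[, , r])
    keep <- !is.na(x) & (is.infinite(cv) | cv > 0)
    if (!any(keep)) next
    sig <- gp$sigma
    fin <- is.finite(cv)
    if (any(fin)) {
      emis <- ifelse(fin, gp$mean * (1 - gp$mean) / pmax(cv, 1), 0)
      sig <- sig + diag(emis, length(emis))
    }
    res <- ifelse(fin, pmax(cv, 1), 2 * gp$obs_n)[keep]
    ll <- ll + capped_gauss_ll(x[keep], gp$mean[keep],
                               sig[keep, keep, drop = FALSE], res)
  }
  ll
}

# Gaussian log-likelihood as a product of capped conditional masses: the
# i-th conditional density (from the Cholesky factor, fixed ordering) times
# the observation resolution 1/res_i, capped at probability one.
capped_gauss_ll <- function(x, mean, sigma, res) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-10 * max(diag(sigma), 1e-12)
    ch <- tryCatch(chol(sigma + jit * diag(nrow(sigma))),
                   error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(psd_repair(sigma, floor = jit) + jit * diag(nrow(sigma)))
    }
  }
  z <- backsolve(ch, x - mean, transpose = TRUE)
  sd_c <- diag(ch)
  lcond <- -0.5 * log(2 * pi) - log(sd_c) - 0.5 * z * z - log(res)
  sum(pmin(lcond, 0))
}

#' Exact single-observation likelihood by quadrature
#'
#' Adaptive quadrature of the binomial emission against the Gaussian state
#' distribution for a single (time, locus, replicate) observation:
#' `integral of Binom(d; c, x) N(x; mu, var) dx` over `[0, 1]`.  Used as a
#' validation oracle for the Gaussian moment-matched emission.
#'
#' @param d derived-allele read count.
#' @param c coverage depth.
#' @param mu,var mean and variance of the latent frequency.
#' @return log-likelihood value.
#' @export
gp_loglik_exact1 <- function(d, c, mu, var) {
  if (var < 1e-14) return(dbinom(d, c, min(max(mu, 0), 1), log = TRUE))
  log(integrate(function(x) dbinom(d, c, x) * dnorm(x, mu, sqrt(var)),
                0, 1, rel.tol = 1e-10)$value)
}
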