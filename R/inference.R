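#' @keywords internal
# Build a cached log-likelihood function ll(s, h) for one focal site and a
# fixed set of companion loci.  Founder tabulations and the observation
# arrays are prepared once; each call assembles the Gaussian approximation
# through the delta-recursion engine (so the s = 0 null is exactly nested).
prepare_fit <- function(arrs, panel, design, focal, companions = integer(0),
                        ne = NULL, map = NULL) {
  loci <- sort(unique(c(focal, companions)))
  init <- founder_init(panel, loci, selected = focal)
  ne <- ne %||% design$n_diploid
  map <- map %||% rec_map(design$r_bp, design$hotspot)
  sub_f <- arrs$freq[, loci, , drop = FALSE]
  sub_c <- arrs$coverage[, loci, , drop = FALSE]
  function(s, h = 0.5, ne_val = ne) {
    th <- model_theta(s = s, h = h, selected = focal, ne = ne_val, map = map)
    gp <- build_gp(init, design, th)
    gp_loglik(sub_f, sub_c, gp)
  }
}

# observation arrays for a data tibble aligned with the panel
data_arrays <- function(data, panel, design) {
  traj_arrays(data, panel$positions, design$generations, design$n_replicates)
}

# fast path for the one-locus fit: same model as prepare_fit() with a
# single locus (one-locus delta recursion, clipped means, Gaussian emission,
# capped conditional masses) without the general assembly overhead
one_locus_ll_fun <- function(x0, freq, cov, tvec, ne, obs_n) {
  tt <- length(tvec)
  r_count <- ncol(freq)
  function(s, h = 0.5) {
    o <- one_locus_moments(x0, s, h, ne, tvec)
    m <- pmin(pmax(o$means, .mean_clip[1]), .mean_clip[2])
    ll <- 0
    for (r in seq_len(r_count)) {
      x <- freq[, r]; cv <- cov[, r]
      keep <- !is.na(x) & (is.infinite(cv) | cv > 0)
      if (!any(keep)) next
      sig <- o$cov
      fin <- is.finite(cv)
      if (any(fin)) {
        sig <- sig + diag(ifelse(fin, m * (1 - m) / pmax(cv, 1), 0), tt)
      }
      res <- ifelse(fin, pmax(cv, 1), 2 * obs_n)[keep]
      ll <- ll + capped_gauss_ll(x[keep], m[keep],
                                 sig[keep, keep, drop = FALSE], res)
    }
    ll
  }
}

#' Likelihood-ratio scan for selection
#'
#' For each requested site, maximises the Gaussian-process log-likelihood
#' over the selection coefficient `s` (bounded scalar search, dominance
#' fixed at `h`) and forms the likelihood-ratio statistic
#' `Lambda = 2 [sup_s log L(s) - log L(0)]`, floored at zero.  With
#' `model_loci > 1`, each site is fit jointly with `model_loci - 1` neutral
#' companion loci (chosen by [choose_companions()] unless supplied).
#'
#' @param data long trajectory tibble (columns `gen`, `rep`, `pos`, `freq`,
#'   `coverage`), e.g. `sim_er_experiment(...)$data` or [read_sync()] output.
#' @param panel the [founder_panel()] of the experiment.
#' @param design the [er_design()].
#' @param sites panel site indices to scan (default: all).
#' @param model_loci number of loci in each fit (1, 3, 5 or 7).
#' @param companions optional fixed companion site indices (used for every
#'   focal site); default chooses per-site companions.
#' @param h dominance parameter held fixed.
#' @param ne effective size (default: `design$n_diploid`).
#' @param s_bounds search interval for `s`.
#' @param tol optimiser tolerance on `s`.
#' @return tibble of class `er_scan` with columns `site`, `pos`, `x0`,
#'   `lambda`, `s_hat`, `loglik0`, `loglik1`, `rank` (by decreasing
#'   `lambda`, ties broken by ascending position).
#' @export
lr_scan <- function(data, panel, design, sites = NULL, model_loci = 1,
                    companions = NULL, h = 0.5, ne = NULL,
                    s_bounds = c(-0.5, 1), tol = 1e-4) {
  sites <- sites %||% seq_along(panel$positions)
  arrs <- data_arrays(data, panel, design)
  x0 <- panel_freqs(panel)
  ne_val <- ne %||% design$n_diploid
  rows <- purrr::map(sites, function(site) {
    comp <- companions %||%
      (if (model_loci > 1) choose_companions(panel, site, model_loci - 1)
       else integer(0))
    comp <- setdiff(comp, site)
    ll <- if (length(comp) == 0) {
      tt <- length(design$generations)
      f <- matrix(arrs$freq[, site, ], nrow = tt)
      cvm <- matrix(arrs$coverage[, site, ], nrow = tt)
      tv <- as.integer(design$generations)
      function(s, h = 0.5) {
        one_locus_ll_cpp(s, h, x0[site], f, cvm, tv, ne_val,
                         design$n_diploid)
      }
    } else {
      prepare_fit(arrs, panel, design, site, comp, ne = ne)
    }
    ll0 <- ll(0, h)
    op <- optimize(function(s) ll(s, h), s_bounds, maximum = TRUE, tol = tol)
    tibble(site = site, pos = panel$positions[site], x0 = x0[site],
           lambda = max(0, 2 * (op$objective - ll0)),
           s_hat = op$maximum, loglik0 = ll0, loglik1 = op$objective)
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- rank_sites(out$lambda, out$pos)
  structure(dplyr::arrange(out, .data$rank), class = c("er_scan", class(out)))
}

# deterministic ranking: decreasing statistic, ties by ascending position
rank_sites <- function(lambda, pos) {
  ord <- order(-lambda, pos)
  r <- integer(length(lambda))
  r[ord] <- seq_along(lambda)
  r
}

#' Rank candidate sites and score localisation accuracy
#'
#' Sites are ranked by decreasing likelihood-ratio statistic, ties broken by
#' ascending genomic position; the top-ranked site is the location estimate.
#' When the true selected site is supplied, the basepair distance from the
#' estimate to the truth and the rank of the truth are reported.
#'
#' @param scan an [lr_scan()] result (or any tibble with `site`, `pos`,
#'   `lambda`).
#' @param true_site optional panel index of the truly selected site.
#' @return list with `ranked` (the reordered tibble), `top` (best site row),
#'   and, when `true_site` is given, `distance` and `rank_of_truth`.
#' @export
localize_sites <- function(scan, true_site = NULL) {
  ranked <- scan[order(rank_sites(scan$lambda, scan$pos)), ]
  out <- list(ranked = ranked, top = ranked[1, ])
  if (!is.null(true_site)) {
    i <- match(true_site, ranked$site)
    if (is.na(i)) abort("true_site not present in the scan")
    out$distance <- abs(ranked$pos[1] - ranked$pos[i])
    out$rank_of_truth <- i
  }
  out
}

#' Empirical null distribution of the maximum LR statistic
#'
#' Simulates neutral (`s = 0`) replicate experiments under the same founder
#' panel and design, scans each with the one-locus (or requested) model, and
#' collects the maximum likelihood-ratio statistic over sites.  P-values for
#' an observed maximum are `(1 + #{null >= obs}) / (n + 1)`.
#'
#' @param panel,design as in [lr_scan()].
#' @param n_sims number of neutral simulations.
#' @param seed master seed.
#' @param sites,model_loci,... passed to [lr_scan()].
#' @param fresh_panels when `TRUE`, draw a new founder panel for every
#'   simulation (matching designs where each simulated experiment has its
#'   own panel); `panel` is then a generator function `function(i)` or the
#'   fixed panel is reused.
#' @return object of class `er_null`: list with sorted `lambda_max`,
#'   `n_sims`, `seed`.
#' @export
empirical_null <- function(panel, design, n_sims = 200, seed = 1,
                           sites = NULL, model_loci = 1, ...) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_sims)
  lam <- vapply(seq_len(n_sims), function(i) {
    pan <- if (is.function(panel)) panel(sub[i]) else panel
    ex <- sim_er_experiment(pan, design, selection = NULL, seed = sub[i])
    sc <- lr_scan(ex$data, pan, design, sites = sites,
                  model_loci = model_loci, ...)
    max(sc$lambda)
  }, numeric(1))
  structure(list(lambda_max = sort(lam), n_sims = n_sims, seed = seed),
            class = "er_null")
}

#' @rdname empirical_null
#' @param null an `er_null` object.
#' @param lambda observed maximum LR statistic(s).
#' @export
null_pvalue <- function(null, lambda) {
  vapply(lambda, function(l) {
    (1 + sum(null$lambda_max >= l)) / (null$n_sims + 1)
  }, numeric(1))
}

#' Empirical ROC curve from null and alternative statistic samples
#'
#' @param null_stats maximum LR statistics under neutral simulation.
#' @param alt_stats maximum LR statistics under the selection alternative.
#' @return tibble with `threshold`, `fpr`, `tpr`, one row per threshold.
#' @export
roc_points <- function(null_stats, alt_stats) {
  stopifnot(length(null_stats) > 0, length(alt_stats) > 0)
  thr <- sort(unique(c(-Inf, null_stats, alt_stats, Inf)))
  tibble(
    threshold = thr,
    fpr = vapply(thr, function(x) mean(null_stats >= x), numeric(1)),
    tpr = vapply(thr, function(x) mean(alt_stats >= x), numeric(1))
  )
}

# interpolated TPR at a given FPR from an ROC tibble
roc_tpr_at <- function(roc, fpr) {
  o <- order(roc$fpr, roc$tpr)
  stats::approx(roc$fpr[o], roc$tpr[o], xout = fpr, ties = max,
                rule = 2)$y
}

#' Choose neutral companion loci for a multi-locus fit
#'
#' Picks `k` sites segregating at intermediate initial frequency
#' (`maf_bounds`), evenly spread around the focal site: targets are placed
#' symmetrically at multiples of `region_length / (k + 2)` from the focal
#' position and the nearest eligible site is taken for each.
#'
#' @param panel a [founder_panel()].
#' @param focal focal site index.
#' @param k number of companions.
#' @param maf_bounds admissible initial-frequency interval.
#' @return integer vector of `<= k` panel site indices.
#' @export
choose_companions <- function(panel, focal, k, maf_bounds = c(0.1, 0.9)) {
  x0 <- panel_freqs(panel)
  cand <- setdiff(which(x0 >= maf_bounds[1] & x0 <= maf_bounds[2]), focal)
  if (length(cand) == 0) return(integer(0))
  m <- ceiling(k / 2)
  step <- panel$region_length / (k + 2)
  offs <- c(-(m:1), 1:m)[seq_len(k) + (k %% 2)]  # symmetric offsets
  targets <- panel$positions[focal] + offs * step
  chosen <- integer(0)
  for (tg in targets) {
    avail <- setdiff(cand, chosen)
    if (length(avail) == 0) break
    chosen <- c(chosen, avail[which.min(abs(panel$positions[avail] - tg))])
  }
  sort(chosen)
}

#' Maximum-likelihood estimate of the selection coefficient
#'
#' Bounded scalar maximisation of the Gaussian-process likelihood over `s`
#' at a known selected site, with dominance fixed (default `h = 1/2`,
#' additive selection).  `model_loci > 1` adds linked neutral companion
#' loci, which sharpens the estimate when frequencies are observed with
#' sequencing noise.
#'
#' @inheritParams lr_scan
#' @param site the (known) selected site index.
#' @return one-row tibble with `s_hat`, `lambda`, `loglik`, `convergence`.
#' @export
estimate_s <- function(data, panel, design, site, model_loci = 1,
                       companions = NULL, h = 0.5, ne = NULL,
                       s_bounds = c(-0.5, 1), tol = 1e-4) {
  sc <- lr_scan(data, panel, design, sites = site, model_loci = model_loci,
                companions = companions, h = h, ne = ne,
                s_bounds = s_bounds, tol = tol)
  tibble(site = site, s_hat = sc$s_hat, lambda = sc$lambda,
         loglik = sc$loglik1)
}

#' Joint maximum-likelihood estimation of dominance and selection
#'
#' Multi-start bounded maximisation over `(h, s)`.  The individual
#' parameters are weakly identified when trajectories are short, but their
#' product `h * s` (the heterozygote advantage under overdominance) is well
#' estimated; the product is returned alongside the components.
#'
#' @inheritParams estimate_s
#' @param s_box,h_box box constraints for the search.
#' @param starts matrix of `(s, h)` starting points (rows); the default uses
#'   four spread starts.
#' @return one-row tibble with `s_hat`, `h_hat`, `hs_hat`, `loglik`,
#'   `convergence`.
#' @export
estimate_hs <- function(data, panel, design, site, model_loci = 1,
                        companions = NULL, ne = NULL,
                        s_box = c(1e-4, 1), h_box = c(-5, 50),
                        starts = NULL) {
  arrs <- data_arrays(data, panel, design)
  comp <- companions %||%
    (if (model_loci > 1) choose_companions(panel, site, model_loci - 1)
     else integer(0))
  ll <- prepare_fit(arrs, panel, design, site, setdiff(comp, site), ne = ne)
  starts <- starts %||% rbind(c(0.01, 1), c(0.01, 10), c(0.05, 2),
                              c(0.1, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(
      optim(starts[i, ], function(p) -ll(p[1], p[2]),
            method = "L-BFGS-B",
            lower = c(s_box[1], h_box[1]), upper = c(s_box[2], h_box[2]),
            control = list(factr = 1e10)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) abort("all (h, s) optimisations failed")
  tibble(site = site, s_hat = best$par[1], h_hat = best$par[2],
         hs_hat = best$par[1] * best$par[2], loglik = -best$value,
         convergence = best$convergence)
}

#' Estimate the effective population size
#'
#' Maximises the neutral multi-locus Gaussian likelihood over `N_e` on a
#' log10 grid spanning `10^log_range`, refined by golden-section search.
#' The likelihood is driven by the magnitude of drift (variance of order
#' `1/(2 N_e)` per generation), so the estimator is precise for small
#' populations and progressively flatter as `N_e` grows; a flat-likelihood
#' flag is raised when the profile varies by less than 2 log-units across
#' the grid.
#'
#' @inheritParams lr_scan
#' @param sites site indices used for estimation (a modest number of
#'   intermediate-frequency sites is sufficient).
#' @param log_range log10 bounds of the search grid.
#' @param grid_n grid resolution.
#' @param sigma_scale internal variance multiplier (used by diagnostics;
#'   scaling all drift variances by `a` shifts the estimate to
#'   approximately `N_e / a`).
#' @return one-row tibble with `ne_hat`, `loglik`, `flat` (logical flag).
#' @export
estimate_ne <- function(data, panel, design, sites, log_range = c(1, 5),
                        grid_n = 17, sigma_scale = 1) {
  arrs <- data_arrays(data, panel, design)
  init <- founder_init(panel, sites)
  map <- rec_map(design$r_bp, design$hotspot)
  sub_f <- arrs$freq[, sites, , drop = FALSE]
  sub_c <- arrs$coverage[, sites, , drop = FALSE]
  ll <- function(log10_ne) {
    th <- model_theta(s = 0, selected = NA, ne = 10^log10_ne, map = map)
    # delta-recursion assembly: the closed-form neutral moments are
    # linear in t/(2N) and degrade over the small-Ne part of the grid
    gp <- build_gp(init, design, th, engine_null = TRUE)
    if (sigma_scale != 1) gp$sigma <- gp$sigma * sigma_scale
    gp_loglik(sub_f, sub_c, gp)
  }
  grid <- seq(log_range[1], log_range[2], length.out = grid_n)
  vals <- vapply(grid, ll, numeric(1))
  # flat profile: the upper end of the grid cannot be distinguished from
  # the maximum (drift signal too weak to bound N_e from above)
  flat <- (max(vals) - vals[grid_n]) < 2
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  op <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-3)
  tibble(ne_hat = 10^op$maximum, loglik = op$objective, flat = flat)
}

#' Estimate the recombination rate inside a hotspot
#'
#' Maximises the neutral multi-locus likelihood over the hotspot intensity
#' multiplier `alpha` (so `r_H = alpha * r_bp`) on a log10 grid with local
#' refinement, using loci sampled inside and outside the declared hotspot
#' interval.  Hotspot boundaries are assumed known.
#'
#' @inheritParams lr_scan
#' @param hotspot list with `start` and `end` (bp) of the hotspot interval.
#' @param sites site indices used in the fit (e.g. 10 inside and 20 outside
#'   the hotspot); at least 2 must fall inside the hotspot.
#' @param log_alpha_range log10 bounds for the multiplier search.
#' @param grid_n grid resolution.
#' @return one-row tibble with `alpha_hat`, `r_h_hat`, `loglik`.
#' @export
estimate_hotspot <- function(data, panel, design, hotspot, sites,
                             log_alpha_range = c(-1, 5), grid_n = 13) {
  inside <- sites[panel$positions[sites] >= hotspot$start &
                    panel$positions[sites] <= hotspot$end]
  if (length(inside) < 2) abort("need at least 2 loci inside the hotspot")
  arrs <- data_arrays(data, panel, design)
  init <- founder_init(panel, sites)
  sub_f <- arrs$freq[, sites, , drop = FALSE]
  sub_c <- arrs$coverage[, sites, , drop = FALSE]
  ll <- function(log10_alpha) {
    map <- rec_map(design$r_bp,
                   list(start = hotspot$start, end = hotspot$end,
                        alpha = 10^log10_alpha))
    th <- model_theta(s = 0, selected = NA, ne = design$n_diploid, map = map)
    gp <- build_gp(init, design, th)
    gp_loglik(sub_f, sub_c, gp)
  }
  grid <- seq(log_alpha_range[1], log_alpha_range[2], length.out = grid_n)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  op <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-3)
  tibble(alpha_hat = 10^op$maximum,
         r_h_hat = 10^op$maximum * design$r_bp, loglik = op$objective)
}

#' Selection strength required to approach fixation in an experiment
#'
#' Averaging over the neutral founder site-frequency spectrum (initial
#' derived-allele counts `k` of `F` with weight `1/k`), the expected
#' selection coefficient needed for the derived allele to reach frequency
#' `x_f` within `T` generations under logistic (additive) growth:
#' `s_fix = (1 / H_{F-1}) * sum_k (1 / (k T)) log[x_f / (1 - x_f) * (F - k) / k]`
#' with `H_n` the harmonic number.  Useful for powering E&R designs.
#'
#' @param t_gens experiment duration `T` in generations.
#' @param n_founders number of founder lines `F`.
#' @param x_f target frequency in `(0, 1)`.
#' @return the design selection coefficient.
#' @export
#' @examples
#' s_fix(50, 200, 0.95)  # about 0.11
s_fix <- function(t_gens, n_founders, x_f) {
  if (t_gens < 1 || n_founders < 2) abort("need T >= 1 and F >= 2")
  if (x_f <= 0 || x_f >= 1) abort("x_f must lie strictly in (0, 1)")
  k <- seq_len(n_founders - 1)
  h_n <- sum(1 / k)
  sum((1 / (k * t_gens)) * log(x_f / (1 - x_f) * (n_founders - k) / k)) / h_n
}
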