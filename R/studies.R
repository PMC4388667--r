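#' Replication studies on simulated E&R experiments
#'
#' These functions regenerate the package's simulation studies: each draws a
#' fresh founder panel per simulation, places selection at a random site,
#' simulates the experiment forward, and applies the estimator or test under
#' study.  They are used by the test suite and the acceptance script, and
#' can be run at any replication count.
#'
#' `study_estimation_cell()` reproduces one cell of the
#' selection-coefficient estimation study: the mean and IQR of the
#' maximum-likelihood estimate of `s` at the (known) selected site for a
#' given model size and coverage depth.  The selected site is conditioned on
#' an intermediate starting frequency (`min_freq`, default 0.1) so that the
#' selected allele is rarely absorbed during the experiment.
#'
#' @param n_sims number of simulated experiments.
#' @param s,h true selection parameters.
#' @param model_loci loci in the fitted model (1 or 5 in the study).
#' @param coverage coverage model (see [coverage_infinite()]).
#' @param generations sampling generations.
#' @param n_founders,region_length,n_diploid,n_replicates design of the
#'   simulated experiments.
#' @param min_freq minimum starting minor-allele frequency for the selected
#'   site (`NULL` to disable conditioning).
#' @param exclude_freq starting-frequency interval to exclude (used by the
#'   overdominance study).
#' @param seed master seed.
#' @return a tibble with one row per simulation.
#' @export
study_estimation_cell <- function(n_sims, s, model_loci = 1,
                                  coverage = coverage_infinite(),
                                  generations = c(10, 20, 30, 40, 50),
                                  n_founders = 200, region_length = 20e3,
                                  n_diploid = 1000, n_replicates = 3,
                                  min_freq = 0.1, seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_sims)
  rows <- purrr::map(seq_len(n_sims), function(i) {
    set.seed(sub[i])
    pan <- sim_founder_panel(n_founders, region_length)
    site <- sample_selected_site(pan, min_freq = min_freq)
    comp <- if (model_loci > 1) {
      choose_companions(pan, site, model_loci - 1)
    } else integer(0)
    des <- er_design(n_diploid = n_diploid, generations = generations,
                     n_replicates = n_replicates, coverage = coverage)
    # only the modelled loci need to be evolved (selection acts at one of
    # them; the rest of the panel does not feed back on their dynamics)
    keep <- sort(unique(c(site, comp)))
    ps <- subset_panel(pan, keep)
    ex <- sim_er_experiment(ps, des, er_selection(match(site, keep), s, 0.5),
                            seed = sub[i] %% 100000000L + 1L)
    est <- suppressWarnings(
      estimate_s(ex$data, ps, des, site = match(site, keep),
                 companions = match(comp, keep)))
    tibble(sim = i, s_hat = est$s_hat, x0 = panel_freqs(pan)[site])
  })
  dplyr::bind_rows(rows)
}

#' @rdname study_estimation_cell
#' @export
study_overdominance <- function(n_sims, s = 0.01, h = 10,
                                exclude_freq = c(0.4, 0.6), min_freq = NULL,
                                generations = c(10, 20, 30, 40, 50),
                                n_founders = 200, region_length = 20e3,
                                n_diploid = 1000, n_replicates = 3,
                                seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_sims)
  rows <- purrr::map(seq_len(n_sims), function(i) {
    set.seed(sub[i])
    pan <- sim_founder_panel(n_founders, region_length)
    site <- sample_selected_site(pan, min_freq = min_freq,
                                 exclude_freq = exclude_freq)
    des <- er_design(n_diploid = n_diploid, generations = generations,
                     n_replicates = n_replicates)
    ps <- subset_panel(pan, site)
    ex <- sim_er_experiment(ps, des, er_selection(1, s, h),
                            seed = sub[i] %% 100000000L + 1L)
    est <- suppressWarnings(estimate_hs(ex$data, ps, des, site = 1))
    tibble(sim = i, s_hat = est$s_hat, h_hat = est$h_hat,
           hs_hat = est$hs_hat, x0 = panel_freqs(pan)[site])
  })
  dplyr::bind_rows(rows)
}

#' @rdname study_estimation_cell
#' @param n_sims_each simulations per arm (selected and neutral).
#' @return `study_power()`: list with `null` and `alt` max-statistic
#'   vectors and the `roc` tibble.
#' @export
study_power <- function(n_sims_each, s = 0.05, n_founders = 20,
                        region_length = 1e5, n_diploid = 1000,
                        n_replicates = 3,
                        generations = c(10, 20, 30, 40, 50), seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 2 * n_sims_each)
  des <- er_design(n_diploid = n_diploid, generations = generations,
                   n_replicates = n_replicates)
  one <- function(seed_i, sel) {
    set.seed(seed_i)
    pan <- sim_founder_panel(n_founders, region_length)
    selection <- if (sel) {
      er_selection(sample.int(length(pan$positions), 1), s, 0.5)
    } else NULL
    ex <- sim_er_experiment(pan, des, selection,
                            seed = seed_i %% 100000000L + 1L)
    sc <- suppressWarnings(lr_scan(ex$data, pan, des, tol = 1e-3))
    max(sc$lambda)
  }
  alt <- vapply(sub[seq_len(n_sims_each)], one, numeric(1), sel = TRUE)
  null <- vapply(sub[n_sims_each + seq_len(n_sims_each)], one, numeric(1),
                 sel = FALSE)
  list(null = null, alt = alt, roc = roc_points(null, alt))
}

#' @rdname study_estimation_cell
#' @return `study_localization()`: tibble with per-simulation `hit`
#'   (top-ranked site is the true site), `distance` and `rank_of_truth`.
#' @export
study_localization <- function(n_sims, s = 0.1, n_founders = 20,
                               region_length = 1e5, n_diploid = 1000,
                               n_replicates = 3,
                               generations = c(10, 20, 30, 40, 50),
                               seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, n_sims)
  des <- er_design(n_diploid = n_diploid, generations = generations,
                   n_replicates = n_replicates)
  rows <- purrr::map(seq_len(n_sims), function(i) {
    set.seed(sub[i])
    pan <- sim_founder_panel(n_founders, region_length)
    site <- sample.int(length(pan$positions), 1)
    ex <- sim_er_experiment(pan, des, er_selection(site, s, 0.5),
                            seed = sub[i] %% 100000000L + 1L)
    sc <- suppressWarnings(lr_scan(ex$data, pan, des, tol = 1e-3))
    loc <- localize_sites(sc, true_site = site)
    tibble(sim = i, hit = loc$distance == 0, distance = loc$distance,
           rank_of_truth = loc$rank_of_truth)
  })
  dplyr::bind_rows(rows)
}
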