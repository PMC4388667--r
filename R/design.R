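#' Describe an evolve-and-resequence experimental design
#'
#' @param n_diploid diploid census size `N` of the experimental population.
#' @param generations strictly increasing positive integers: the generations
#'   at which pooled sequencing is performed.
#' @param n_replicates number of experimental replicates `R`, all started
#'   from the same founding population.
#' @param r_bp background recombination rate per basepair per generation.
#' @param coverage a coverage model from [coverage_infinite()],
#'   [coverage_poisson()] or [coverage_empirical()]; `Inf` and a single
#'   number are accepted as shorthands.
#' @param hotspot optional recombination hotspot: a list with elements
#'   `start`, `end` (bp, the hotspot interval) and `alpha` (multiplier on
#'   `r_bp` inside the interval).
#' @return an object of class `er_design`.
#' @export
#' @examples
#' er_design()  # the default: N = 1000, t = 10..50, R = 3, exact frequencies
er_design <- function(n_diploid = 1000,
                      generations = c(10, 20, 30, 40, 50),
                      n_replicates = 3,
                      r_bp = 2e-8,
                      coverage = coverage_infinite(),
                      hotspot = NULL) {
  if (n_diploid < 1) abort("n_diploid must be >= 1")
  if (length(generations) < 1 || any(generations < 1) ||
      any(diff(generations) <= 0)) {
    abort("generations must be strictly increasing positive integers")
  }
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (r_bp < 0) abort("r_bp must be non-negative")
  if (is.numeric(coverage)) {
    coverage <- if (is.infinite(coverage)) coverage_infinite()
                else coverage_poisson(coverage)
  }
  if (!is.null(hotspot)) {
    stopifnot(hotspot$start < hotspot$end, hotspot$alpha > 0)
  }
  structure(
    list(n_diploid = as.integer(n_diploid),
         generations = as.integer(generations),
         n_replicates = as.integer(n_replicates),
         r_bp = r_bp, coverage = coverage, hotspot = hotspot),
    class = "er_design"
  )
}

#' @export
print.er_design <- function(x, ...) {
  cat(sprintf("<er_design> N = %d, t = {%s}, R = %d, r = %g /bp/gen, coverage: %s\n",
              x$n_diploid, paste(x$generations, collapse = ", "),
              x$n_replicates, x$r_bp, x$coverage$model))
  invisible(x)
}

#' Coverage models for pooled sequencing
#'
#' `coverage_infinite()` records population frequencies without error;
#' `coverage_poisson()` draws the per-site read depth from a Poisson
#' distribution with mean `mean`; `coverage_empirical()` resamples depths
#' from an observed depth distribution (a plain vector of non-negative
#' integers, e.g. read from a one-depth-per-line text file).
#'
#' @param mean mean Poisson coverage depth `C` (> 0).
#' @param depths vector of observed depths to resample from.
#' @return a coverage-model list with element `model` and parameters.
#' @export
coverage_infinite <- function() {
  structure(list(model = "infinite"), class = "er_coverage")
}

#' @rdname coverage_infinite
#' @export
coverage_poisson <- function(mean) {
  if (mean <= 0) abort("poisson coverage mean must be > 0")
  structure(list(model = "poisson", mean = mean), class = "er_coverage")
}

#' @rdname coverage_infinite
#' @export
coverage_empirical <- function(depths) {
  depths <- as.integer(depths)
  if (length(depths) == 0) abort("empirical coverage model needs a non-empty depth distribution")
  if (any(depths < 0)) abort("depths must be non-negative")
  structure(list(model = "empirical", depths = depths), class = "er_coverage")
}

#' Describe selection acting on one site
#'
#' Relative fitnesses are 1, `1 + h s` and `1 + s` for the ancestral
#' homozygote, the heterozygote and the derived homozygote at the selected
#' site.  `h = 0.5` is additive (genic) selection; `h > 1` with small `s`
#' gives heterozygote advantage (overdominance).
#'
#' @param site column index of the selected site in the founder panel, or
#'   `NA` for a neutral experiment.
#' @param s selection coefficient (must satisfy `1 + s > 0`).
#' @param h dominance parameter (must satisfy `1 + h s > 0`).
#' @return an object of class `er_selection`.
#' @export
er_selection <- function(site = NA_integer_, s = 0, h = 0.5) {
  if (1 + s <= 0 || 1 + h * s <= 0) {
    abort("invalid fitnesses: need 1 + s > 0 and 1 + h*s > 0")
  }
  structure(list(site = as.integer(site), s = s, h = h),
            class = "er_selection")
}
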