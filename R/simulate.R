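#' Evolve a diploid population forward in time
#'
#' Discrete-generation Wright-Fisher reproduction with random mating: each of
#' the `2N` gametes of the next generation draws a diploid parent with
#' probability proportional to its fitness (1, `1 + hs`, `1 + s` according to
#' the genotype at the selected site; uniform under neutrality) and is formed
#' by meiosis with crossovers between adjacent sites.  The crossover
#' fraction between adjacent sites at distance `d` bp is `min(r_bp * d, 0.5)`
#' (plus any hotspot contribution), with no interference.
#'
#' With `deterministic = TRUE` the infinite-population limit is returned
#' instead: the exact haplotype-frequency map (selection followed by
#' recombination) is iterated from the current haplotype frequencies.  This
#' mode tabulates all `2^K` haplotypes and is only available for `K <= 12`.
#'
#' @param population integer matrix of `2N` haplotype rows (see
#'   [clone_founders()]).
#' @param positions basepair positions of the columns of `population`.
#' @param design an [er_design()]; `n_diploid` must match the population.
#' @param selection an [er_selection()] (or `NULL` for neutrality).
#' @param deterministic iterate the deterministic map instead of sampling.
#' @return numeric matrix `T x K` of derived-allele frequencies at
#'   `design$generations`.
#' @export
evolve_population <- function(population, positions, design,
                              selection = NULL, deterministic = FALSE) {
  if (nrow(population) == 0) abort("empty population")
  if (nrow(population) != 2L * design$n_diploid) {
    abort("population size inconsistent with design$n_diploid")
  }
  sel <- selection %||% er_selection()
  k <- ncol(population)
  if (!is.na(sel$site) && (sel$site < 1 || sel$site > k)) {
    abort("selected site index out of range")
  }
  if (deterministic) {
    return(evolve_deterministic(population, positions, design, sel))
  }
  rf <- interval_rec_fractions(positions, design)
  lambda <- haldane_intensity(rf)
  freqs <- evolve_pool_cpp(population, lambda,
                           if (is.na(sel$site)) -1L else sel$site - 1L,
                           sel$s, sel$h, as.integer(design$generations))
  dimnames(freqs) <- list(gen = design$generations, site = seq_len(k))
  freqs
}

# recombination fraction for each adjacent-site interval, including any
# hotspot contribution from the design
interval_rec_fractions <- function(positions, design) {
  k <- length(positions)
  if (k < 2) return(numeric(0))
  map <- rec_map(design$r_bp, design$hotspot)
  vapply(seq_len(k - 1), function(i) {
    rec_fraction(positions[i], positions[i + 1], map)
  }, numeric(1))
}

# Poisson crossover intensity giving an exact marginal switch probability r
# per interval (inverse Haldane map); r is capped just below 1/2.
haldane_intensity <- function(r) {
  r <- pmin(r, 0.5 - 1e-9)
  -0.5 * log(1 - 2 * r)
}

evolve_deterministic <- function(population, positions, design, sel) {
  k <- ncol(population)
  if (k > 12) abort("deterministic mode tabulates 2^K haplotypes; K <= 12 required")
  z <- tabulate_haplotypes(population)
  rf <- interval_rec_fractions(positions, design)
  model <- wf_model(n_loci = k,
                    selected = if (is.na(sel$site)) NA else sel$site,
                    s = sel$s, h = sel$h, rec = rf,
                    n_diploid = design$n_diploid)
  amat <- allele_matrix(k)
  tmax <- max(design$generations)
  out <- matrix(NA_real_, length(design$generations), k)
  ti <- 1L
  for (t in seq_len(tmax)) {
    z <- hap_transition(z, model)
    if (t == design$generations[ti]) {
      out[ti, ] <- as.numeric(amat %*% z)
      ti <- ti + 1L
      if (ti > length(design$generations)) break
    }
  }
  dimnames(out) <- list(gen = design$generations, site = seq_len(k))
  out
}

# empirical haplotype frequencies (2^K vector, hap_index order) of a pool
tabulate_haplotypes <- function(population) {
  k <- ncol(population)
  idx <- hap_index(population)
  as.numeric(tabulate(idx, nbins = 2^k)) / nrow(population)
}

# haplotype index convention: alleles a_1..a_L (1 = derived); index
# 1 + sum (1 - a_l) * 2^(L - l), so (1,1,..,1) -> 1 and (0,..,0) -> 2^L.
# This puts the fully derived haplotype first, matching the (A1A1, A1A0,
# A0A1, A0A0) ordering used for two-locus formulas.
hap_index <- function(alleles) {
  alleles <- if (is.matrix(alleles)) alleles else matrix(alleles, nrow = 1)
  l <- ncol(alleles)
  1L + as.integer((1 - alleles) %*% 2^((l - 1):0))
}

# L x 2^L matrix mapping haplotype frequencies to marginal derived-allele
# frequencies
allele_matrix <- function(l) {
  m <- 2^l
  a <- matrix(0, l, m)
  for (h in seq_len(m)) {
    bits <- 1 - as.integer(intToBits(h - 1))[l:1]  # little-endian decode
    a[, h] <- bits
  }
  a
}

#' Simulate pooled sequencing of allele-frequency trajectories
#'
#' Coverage is drawn per (generation, site, replicate) from the coverage
#' model and the derived-allele read count is Binomial(coverage, frequency).
#' With infinite coverage the population frequencies are returned verbatim
#' and coverage is flagged `Inf`.
#'
#' @param freqs numeric array `T x K x R` (or matrix `T x K`) of population
#'   frequencies in `[0, 1]`.
#' @param coverage a coverage model (see [coverage_infinite()]).
#' @return list with integer arrays `counts` and `coverages` (both `NA` for
#'   the infinite model) and the numeric array `freqs` of observed
#'   frequencies (count/coverage, or the input when coverage is infinite;
#'   `NaN` where coverage is 0).
#' @export
sim_pool_seq <- function(freqs, coverage = coverage_infinite()) {
  if (length(dim(freqs)) == 2) dim(freqs) <- c(dim(freqs), 1)
  stopifnot(all(freqs >= 0 & freqs <= 1, na.rm = TRUE))
  if (coverage$model == "infinite") {
    return(list(counts = NULL, coverages = NULL, freqs = freqs,
                infinite = TRUE))
  }
  n <- length(freqs)
  cov <- switch(coverage$model,
    poisson = rpois(n, coverage$mean),
    empirical = coverage$depths[sample.int(length(coverage$depths), n,
                                           replace = TRUE)],
    abort("unknown coverage model"))
  cnt <- rbinom(n, cov, as.numeric(freqs))
  dim(cov) <- dim(cnt) <- dim(freqs)
  list(counts = cnt, coverages = cov, freqs = cnt / cov, infinite = FALSE)
}

#' Simulate a complete evolve-and-resequence experiment
#'
#' Composes [clone_founders()], [evolve_population()] (independently per
#' replicate, identical starting conditions) and [sim_pool_seq()].  Each
#' replicate and the sequencing stage use independent RNG streams derived
#' from the master seed by drawing sub-seeds from the master stream, so the
#' whole experiment is reproducible from `seed`.
#'
#' @param panel a [founder_panel()].
#' @param design an [er_design()].
#' @param selection an [er_selection()] or `NULL`.
#' @param seed master seed (integer) or `NULL` to use the current RNG state.
#' @return an object of class `er_experiment`: a list with
#'   \describe{
#'     \item{data}{long tibble with columns `gen`, `rep`, `site`, `pos`,
#'       `count`, `coverage`, `freq` (observed frequency).}
#'     \item{truth}{numeric array `T x K x R` of true population
#'       frequencies.}
#'     \item{panel, design, selection, seed}{the inputs.}
#'   }
#' @export
#' @examples
#' p <- sim_founder_panel(20, 2000, n_sites = 10, seed = 1)
#' ex <- sim_er_experiment(p, er_design(n_diploid = 200), seed = 1)
#' head(ex$data)
sim_er_experiment <- function(panel, design, selection = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max, design$n_replicates + 1L)
  pop <- suppressWarnings(clone_founders(panel, design$n_diploid))
  tvec <- design$generations
  k <- ncol(panel$haplotypes)
  truth <- array(NA_real_, c(length(tvec), k, design$n_replicates))
  for (r in seq_len(design$n_replicates)) {
    set.seed(sub[r])
    truth[, , r] <- evolve_population(pop, panel$positions, design, selection)
  }
  set.seed(sub[design$n_replicates + 1L])
  seq_out <- sim_pool_seq(truth, design$coverage)
  grid <- expand.grid(gen = tvec, site = seq_len(k),
                      rep = seq_len(design$n_replicates))
  data <- tibble(
    gen = grid$gen,
    rep = grid$rep,
    site = grid$site,
    pos = panel$positions[grid$site],
    count = if (seq_out$infinite) NA_integer_ else as.integer(seq_out$counts),
    coverage = if (seq_out$infinite) Inf else as.numeric(seq_out$coverages),
    freq = as.numeric(seq_out$freqs)
  )
  structure(
    list(data = data, truth = truth, panel = panel, design = design,
         selection = selection, seed = seed),
    class = "er_experiment"
  )
}

#' @export
print.er_experiment <- function(x, ...) {
  cat(sprintf("<er_experiment> %d sites x %d generations x %d replicates\n",
              dim(x$truth)[2], dim(x$truth)[1], dim(x$truth)[3]))
  if (!is.null(x$selection) && !is.na(x$selection$site)) {
    cat(sprintf("  selection: s = %g, h = %g at site %d (pos %g)\n",
                x$selection$s, x$selection$h, x$selection$site,
                x$panel$positions[x$selection$site]))
  }
  invisible(x)
}

#' @describeIn sim_er_experiment the long data tibble.
#' @param x an `er_experiment`.
#' @param ... unused.
#' @method tidy er_experiment
#' @export
tidy.er_experiment <- function(x, ...) x$data

# convert a long trajectory tibble into T x K x R arrays aligned with a
# position vector; entries absent from the tibble stay NA
traj_arrays <- function(data, positions, generations, n_replicates) {
  tt <- length(generations)
  k <- length(positions)
  freq <- cov <- array(NA_real_, c(tt, k, n_replicates))
  gi <- match(data$gen, generations)
  si <- match(data$pos, positions)
  ri <- data$rep
  ok <- !is.na(gi) & !is.na(si)
  idx <- cbind(gi[ok], si[ok], ri[ok])
  freq[idx] <- data$freq[ok]
  cov[idx] <- if (all(is.infinite(data$coverage))) Inf else data$coverage[ok]
  list(freq = freq, coverage = cov)
}
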