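#' Founder haplotype panels
#'
#' A founder panel holds the `F x K` matrix of 0/1 alleles carried by the
#' (assumed homozygous) founder lines of an E&R experiment, together with the
#' basepair position of each site.  The panel is the source of the initial
#' allele frequencies and of the linkage disequilibrium that the multi-locus
#' likelihood exploits; the minimum minor allele frequency in a panel of `F`
#' lines is `1/F`.
#'
#' @param haplotypes integer/numeric matrix with one row per founder line and
#'   one column per segregating site; entries must be 0 or 1 and every column
#'   must be segregating (mean strictly between 0 and 1).
#' @param positions strictly increasing 1-based basepair coordinates, one per
#'   column of `haplotypes`.
#' @param region_length length of the simulated/observed region in basepairs.
#' @return An object of class `founder_panel`: a list with elements
#'   `haplotypes`, `positions` and `region_length`.
#' @seealso [sim_founder_panel()] to generate a panel, [read_founders()] /
#'   [write_founders()] for file exchange.
#' @export
#' @examples
#' founder_panel(rbind(c(0, 1), c(1, 0)), positions = c(100, 200),
#'               region_length = 1000)
founder_panel <- function(haplotypes, positions,
                          region_length = max(positions)) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L))) {
    abort("founder haplotypes must be a 0/1 matrix")
  }
  if (length(positions) != ncol(haplotypes)) {
    abort("need one position per site")
  }
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0)) {
    abort("positions must be strictly increasing (duplicates not allowed)")
  }
  if (any(positions < 1) || any(positions > region_length)) {
    abort("positions must lie in [1, region_length]")
  }
  cm <- colMeans(haplotypes)
  if (any(cm <= 0 | cm >= 1)) {
    abort("every site must be segregating among the founders (no monomorphic columns)")
  }
  structure(
    list(haplotypes = haplotypes, positions = positions,
         region_length = as.numeric(region_length)),
    class = "founder_panel"
  )
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d lines x %d sites over %s bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              format(x$region_length, big.mark = ",")))
  invisible(x)
}

#' @export
dim.founder_panel <- function(x) dim(x$haplotypes)

#' Initial allele frequencies of a panel
#' @param panel a [founder_panel()].
#' @return numeric vector of per-site derived-allele frequencies.
#' @export
panel_freqs <- function(panel) colMeans(panel$haplotypes)

#' @describeIn founder_panel one row per site with position, allele count and
#'   frequency.
#' @param x a `founder_panel`.
#' @param ... unused.
#' @method tidy founder_panel
#' @export
tidy.founder_panel <- function(x, ...) {
  tibble(
    site = seq_along(x$positions),
    pos = x$positions,
    count = as.integer(colSums(x$haplotypes)),
    freq = colMeans(x$haplotypes)
  )
}

#' Simulate a founder haplotype panel
#'
#' Generates a panel of `n_founders` haplotypes whose per-site allele counts
#' `k` (out of `F`) follow the neutral site-frequency spectrum (probability
#' proportional to `1/k`, `k = 1, ..., F-1`) and whose linkage disequilibrium
#' decays with basepair distance.  LD is induced by a block-copying scheme:
#' the region is cut into blocks whose lengths are exponential with mean
#' `ld_scale_bp`; within a block all sites draw their carrier sets as nested
#' prefixes of one shared permutation of the founder lines, so nearby sites
#' are in strong (D' = 1) association while distant sites are independent.
#'
#' The default number of sites is `theta_bp * H(F-1) * region_length`, with
#' `H` the harmonic number: the expected number of segregating sites in a
#' sample of `F` chromosomes from a coalescent population with per-basepair
#' diversity `theta_bp`.  The default `theta_bp = 0.0035` reproduces typical
#' segregating-site densities for a Drosophila-sized natural population, and
#' the default `ld_scale_bp = 12.5` corresponds to `1 / (4 N r)` with
#' `N = 1e6` and `r = 2e-8` per bp per generation.
#'
#' @param n_founders number of founder lines `F` (>= 2).
#' @param region_length region size in basepairs.
#' @param n_sites number of segregating sites to place; default derived from
#'   `theta_bp` as described above.
#' @param theta_bp per-basepair diversity used for the default site count.
#' @param ld_scale_bp expected haplotype-block length in basepairs.
#' @param seed optional integer seed for reproducibility.
#' @return a [founder_panel()].
#' @export
#' @examples
#' p <- sim_founder_panel(20, 1e4, seed = 1)
#' min(pmin(panel_freqs(p), 1 - panel_freqs(p))) >= 1 / 20
sim_founder_panel <- function(n_founders, region_length, n_sites = NULL,
                              theta_bp = 0.0035, ld_scale_bp = 12.5,
                              seed = NULL) {
  if (n_founders < 2) abort("need at least 2 founder lines for segregation")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_sites)) {
    n_sites <- max(1L, round(theta_bp * sum(1 / seq_len(n_founders - 1)) *
                               region_length))
  }
  if (n_sites > region_length) {
    abort("cannot place more sites than basepairs in the region")
  }
  positions <- sort(sample.int(region_length, n_sites))
  # neutral SFS allele counts
  k <- sample(seq_len(n_founders - 1), n_sites, replace = TRUE,
              prob = 1 / seq_len(n_founders - 1))
  # block-copying carrier assignment
  haps <- matrix(0L, n_founders, n_sites)
  perm <- sample.int(n_founders)
  last_pos <- positions[1]
  for (j in seq_len(n_sites)) {
    gap <- positions[j] - last_pos
    if (j > 1 && runif(1) < 1 - exp(-gap / ld_scale_bp)) {
      perm <- sample.int(n_founders)
    }
    haps[perm[seq_len(k[j])], j] <- 1L
    last_pos <- positions[j]
  }
  founder_panel(haps, positions, region_length)
}

#' Clone founder lines into a diploid starting population
#'
#' Each founder haplotype is copied `2N / F` times to form the `2N` haploid
#' genomes of the founding diploid population, mimicking the use of
#' (nearly) homozygous recombinant inbred lines.  When `2N` is not divisible
#' by `F` the remaining copies are distributed round-robin over the first
#' founders and a warning is emitted.
#'
#' @param panel a [founder_panel()].
#' @param n_diploid diploid census size `N`.
#' @return integer matrix of `2N` rows (haplotypes) by `K` sites; haplotypes
#'   `2i - 1` and `2i` form individual `i`.  The founder index of each row is
#'   attached as attribute `"founder"`.
#' @export
#' @examples
#' p <- sim_founder_panel(2, 1000, n_sites = 3, seed = 1)
#' pop <- clone_founders(p, 2)
#' table(attr(pop, "founder"))  # each founder copied twice
clone_founders <- function(panel, n_diploid) {
  f <- nrow(panel$haplotypes)
  n_hap <- 2L * as.integer(n_diploid)
  base <- n_hap %/% f
  rem <- n_hap %% f
  copies <- rep(base, f)
  if (rem > 0) {
    copies[seq_len(rem)] <- copies[seq_len(rem)] + 1L
    warn(sprintf(
      "2N = %d is not divisible by F = %d; distributing %d extra copies round-robin",
      n_hap, f, rem))
  }
  idx <- rep(seq_len(f), times = copies)
  pop <- panel$haplotypes[idx, , drop = FALSE]
  attr(pop, "founder") <- idx
  pop
}

#' Sample a site to place under selection
#'
#' Picks a panel site uniformly at random, optionally conditioning its
#' initial derived-allele frequency: `min_freq` keeps the frequency inside
#' `[min_freq, 1 - min_freq]` (estimation studies condition on intermediate
#' starting frequencies so the selected allele is unlikely to be absorbed
#' during the experiment), and `exclude_freq` removes an interval (the
#' overdominance study excludes starts near the interior equilibrium 1/2).
#'
#' @param panel a [founder_panel()].
#' @param min_freq optional minimum minor-allele starting frequency.
#' @param exclude_freq optional closed interval `c(lo, hi)` of starting
#'   frequencies to exclude.
#' @return a site index.
#' @export
sample_selected_site <- function(panel, min_freq = NULL,
                                 exclude_freq = NULL) {
  x0 <- panel_freqs(panel)
  ok <- rep(TRUE, length(x0))
  if (!is.null(min_freq)) ok <- ok & x0 >= min_freq & x0 <= 1 - min_freq
  if (!is.null(exclude_freq)) {
    ok <- ok & !(x0 >= exclude_freq[1] & x0 <= exclude_freq[2])
  }
  if (!any(ok)) abort("no site satisfies the frequency condition")
  which(ok)[sample.int(sum(ok), 1)]
}

#' Restrict a panel to a subset of sites
#'
#' Keeps the selected columns (and their positions) of a founder panel.
#' Useful for estimation studies where only the modelled loci need to be
#' evolved: with selection acting at a modelled locus, the joint dynamics of
#' the modelled loci do not depend on the other neutral sites.
#'
#' @param panel a [founder_panel()].
#' @param sites site indices to keep.
#' @return a [founder_panel()] over the kept sites; the original site
#'   indices are attached as attribute `"parent_sites"`.
#' @export
subset_panel <- function(panel, sites) {
  sites <- sort(unique(sites))
  out <- founder_panel(panel$haplotypes[, sites, drop = FALSE],
                       panel$positions[sites], panel$region_length)
  attr(out, "parent_sites") <- sites
  out
}
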