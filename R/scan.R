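#' Minor-allele-frequency filter for trajectory data
#'
#' A site is retained only if its observed frequency lies inside the closed
#' interval `maf_bounds` at every sampled generation and in every replicate.
#' Filtering out sites that approach the boundaries protects the Gaussian
#' approximation, which degrades near fixation or loss.
#'
#' @param data long trajectory tibble (columns `site` or `pos`, `freq`).
#' @param maf_bounds closed frequency interval, default `[0.1, 0.9]`.
#' @return integer vector of retained site indices (values of the `site`
#'   column; positions when only `pos` is present).
#' @export
maf_filter <- function(data, maf_bounds = c(0.1, 0.9)) {
  key <- if ("site" %in% names(data)) "site" else "pos"
  ok <- dplyr::summarise(
    dplyr::group_by(data, .data[[key]]),
    keep = all(!is.na(.data$freq) & .data$freq >= maf_bounds[1] &
                 .data$freq <= maf_bounds[2]),
    .groups = "drop")
  sort(ok[[key]][ok$keep])
}

#' Average a per-site statistic in non-overlapping windows
#'
#' Windows are fixed-width, half-open `[start, end)`, anchored at basepair 1.
#' Windows containing no sites are reported with `NA` (missing), not zero.
#'
#' @param scan tibble with columns `pos` and `lambda` (e.g. [lr_scan()]).
#' @param window_size window width in basepairs (> 0).
#' @param region_length total region length; defaults to the largest
#'   position observed.
#' @return tibble with `window`, `start`, `end`, `n_snps`, `mean_lambda`.
#' @export
window_average <- function(scan, window_size, region_length = NULL) {
  if (window_size <= 0) abort("window_size must be positive")
  region_length <- region_length %||% max(scan$pos)
  n_win <- ceiling(region_length / window_size)
  win <- pmin(floor((scan$pos - 1) / window_size) + 1, n_win)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(window = win, lambda = scan$lambda), .data$window),
    n_snps = dplyr::n(), mean_lambda = mean(.data$lambda), .groups = "drop")
  out <- tibble(window = seq_len(n_win),
                start = (seq_len(n_win) - 1) * window_size + 1,
                end = pmin(seq_len(n_win) * window_size + 1,
                           region_length + 1))
  out <- dplyr::left_join(out, agg, by = "window")
  out$n_snps[is.na(out$n_snps)] <- 0L
  out
}

#' Nominate candidate regions from windowed LR statistics
#'
#' Automates the region-nomination step of a two-pass scan: windows whose
#' mean statistic exceeds the `1 - q` empirical quantile (over non-empty
#' windows) are selected and merged when adjacent.  The quantile rule is a
#' reproducible stand-in for nomination by visual inspection; `q` is
#' configurable.
#'
#' @param windows a [window_average()] result.
#' @param q upper tail fraction of windows to nominate (default 0.01).
#' @param chrom chromosome label attached to the regions.
#' @return tibble of class `er_regions` with `chrom`, `start`, `end`
#'   (half-open), `n_windows`, `mean_lambda`.
#' @export
candidate_regions <- function(windows, q = 0.01, chrom = "chr1") {
  nonempty <- windows[windows$n_snps > 0, ]
  if (nrow(nonempty) == 0) return(tibble(chrom = character(0),
                                         start = numeric(0), end = numeric(0),
                                         n_windows = integer(0),
                                         mean_lambda = numeric(0)))
  thr <- quantile(nonempty$mean_lambda, 1 - q, names = FALSE)
  # strictly above the threshold: a flat statistic nominates nothing
  hit <- nonempty[nonempty$mean_lambda > thr, ]
  if (nrow(hit) == 0) {
    return(tibble(chrom = character(0), start = numeric(0),
                  end = numeric(0), n_windows = integer(0),
                  mean_lambda = numeric(0)))
  }
  hit <- hit[order(hit$window), ]
  grp <- cumsum(c(1, diff(hit$window) > 1))
  dplyr::summarise(
    dplyr::group_by(tibble(grp = grp, hit), .data$grp),
    chrom = chrom, start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(), mean_lambda = mean(.data$mean_lambda),
    .groups = "drop")[, c("chrom", "start", "end", "n_windows",
                          "mean_lambda")]
}

#' Multi-locus refit of a candidate region
#'
#' Fixes `model_loci - 1` neutral flanking SNPs at multiples of `spacing`
#' basepairs from the midpoint of the region (nearest retained SNP to each
#' prescribed offset, required within `spacing / 2`), then evaluates every
#' retained site inside the region as the putative selected locus of a
#' `model_loci`-locus model.
#'
#' @inheritParams lr_scan
#' @param region one row of [candidate_regions()] (or a list with `start`,
#'   `end`).
#' @param spacing flanking-SNP spacing in basepairs (default 250 kb).
#' @param maf_bounds frequency filter applied to both in-region sites and
#'   flanker candidates.
#' @return an [lr_scan()] tibble restricted to the region, with the flanker
#'   site indices attached as attribute `"flankers"`.
#' @export
refit_region <- function(data, panel, design, region, model_loci = 5,
                         spacing = 250e3, maf_bounds = c(0.1, 0.9), ...) {
  keep <- maf_filter(data, maf_bounds)
  pos <- panel$positions
  inside <- intersect(keep, which(pos >= region$start & pos < region$end))
  if (length(inside) == 0) abort("no retained sites inside the region")
  if (model_loci == 1) {
    return(lr_scan(data, panel, design, sites = inside, model_loci = 1, ...))
  }
  mid <- (region$start + region$end) / 2
  m <- (model_loci - 1) / 2
  offsets <- c(-(m:1), 1:m) * spacing
  cand <- setdiff(keep, inside)
  flank <- integer(0)
  cur_spacing <- spacing
  for (off in offsets) {
    avail <- setdiff(cand, flank)
    if (length(avail) == 0) break
    j <- avail[which.min(abs(pos[avail] - (mid + off)))]
    if (abs(pos[j] - (mid + off)) > cur_spacing / 2) {
      # insufficient SNPs near the prescribed offset: fall back to the
      # nearest available site at the widest usable spacing
      warn(sprintf(
        "no flanking SNP within %g bp of offset %+g; using nearest available",
        cur_spacing / 2, off))
    }
    flank <- c(flank, j)
  }
  out <- lr_scan(data, panel, design, sites = inside,
                 model_loci = length(flank) + 1, companions = sort(flank),
                 ...)
  attr(out, "flankers") <- sort(flank)
  out
}

#' Intersect the top-k candidate lists of several model sizes
#'
#' @param scans list of scan tibbles (one per model size), each with `site`
#'   and `lambda`.
#' @param k list length to take from each scan (default 100).
#' @return tibble of the sites present in every top-k list, ordered by the
#'   maximum `lambda` across models (descending).
#' @export
top_k_intersection <- function(scans, k = 100) {
  stopifnot(length(scans) >= 1)
  tops <- lapply(scans, function(sc) {
    sc$site[order(rank_sites(sc$lambda, sc$pos))][seq_len(min(k, nrow(sc)))]
  })
  common <- Reduce(intersect, tops)
  if (length(common) == 0) {
    return(tibble(site = integer(0), pos = numeric(0), max_lambda = numeric(0)))
  }
  lam <- vapply(common, function(s) {
    max(vapply(scans, function(sc) {
      v <- sc$lambda[sc$site == s]
      if (length(v)) max(v) else -Inf
    }, numeric(1)))
  }, numeric(1))
  pos <- vapply(common, function(s) {
    for (sc in scans) if (s %in% sc$site) return(sc$pos[sc$site == s][1])
    NA_real_
  }, numeric(1))
  out <- tibble(site = common, pos = pos, max_lambda = lam)
  out[order(-out$max_lambda, out$pos), ]
}

#' Two-pass genome scan for selected sites
#'
#' Pass 1: one-locus LR scan of all sites passing the MAF filter, window
#' averaging, and nomination of candidate regions by the empirical-quantile
#' rule.  Pass 2: multi-locus refits (default 3-, 5- and 7-locus models with
#' flanking neutral SNPs at multiples of `spacing`) of every site in each
#' candidate region, followed by the intersection of the per-model top-k
#' lists.
#'
#' @inheritParams lr_scan
#' @param maf_bounds retention interval for observed frequencies.
#' @param window_size pass-1 window width (bp).
#' @param q upper-tail window fraction nominated as candidate regions.
#' @param model_sizes multi-locus model sizes for pass 2.
#' @param spacing flanking-SNP spacing (bp).
#' @param top_k list length for the final intersection.
#' @param pass1_only stop after region nomination.
#' @return object of class `er_scan_result`: list with `pass1` (scan
#'   tibble), `windows`, `regions`, `refits` (per model size), `candidates`
#'   (final intersection tibble), and `log` (character vector of filter
#'   counts and decisions).
#' @export
run_scan <- function(data, panel, design, maf_bounds = c(0.1, 0.9),
                     window_size = 10e3, q = 0.01,
                     model_sizes = c(3, 5, 7), spacing = 250e3,
                     top_k = 100, pass1_only = FALSE, ...) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  keep <- maf_filter(data, maf_bounds)
  say("maf_filter: retained %d of %d sites in [%g, %g]",
      length(keep), length(panel$positions), maf_bounds[1], maf_bounds[2])
  if (length(keep) == 0) abort("no sites pass the MAF filter")
  pass1 <- lr_scan(data, panel, design, sites = keep, model_loci = 1, ...)
  win <- window_average(pass1, window_size,
                        region_length = panel$region_length)
  regions <- candidate_regions(win, q = q)
  say("pass1: %d windows of %g bp, %d candidate region(s)",
      nrow(win), window_size, nrow(regions))
  out <- list(pass1 = pass1, windows = win, regions = regions,
              refits = NULL, candidates = NULL, log = log)
  if (pass1_only || nrow(regions) == 0) {
    out$log <- log
    return(structure(out, class = "er_scan_result"))
  }
  refits <- list()
  for (ksz in model_sizes) {
    per_region <- lapply(seq_len(nrow(regions)), function(i) {
      refit_region(data, panel, design, regions[i, ], model_loci = ksz,
                   spacing = spacing, maf_bounds = maf_bounds, ...)
    })
    refits[[as.character(ksz)]] <- dplyr::bind_rows(per_region)
    say("pass2: %d-locus model, %d sites refit", ksz,
        nrow(refits[[as.character(ksz)]]))
  }
  out$refits <- refits
  out$candidates <- top_k_intersection(refits, k = top_k)
  say("intersection of top-%d lists: %d candidate SNP(s)", top_k,
      nrow(out$candidates))
  out$log <- log
  structure(out, class = "er_scan_result")
}

#' @export
print.er_scan_result <- function(x, ...) {
  cat("<er_scan_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
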