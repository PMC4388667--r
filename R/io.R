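#' Read and write sync-style pool-seq files
#'
#' The sync convention stores one line per site: chromosome, 1-based
#' position, reference base, then one `A:T:C:G:N:del` count sextet per
#' sample.  `read_sync()` maps each sample column to a (generation,
#' replicate) pair via `sample_map` and extracts the derived-allele count
#' and total coverage; `write_sync()` writes trajectories with the derived
#' allele on a fixed base (default `T`) and the remaining reads on the
#' ancestral base (default `A`).
#'
#' @param path file path.
#' @param sample_map tibble/data.frame with columns `column` (sample column
#'   number, 1 = first sextet), `gen`, `rep`.
#' @param derived_base single base in `A,T,C,G` carrying the derived allele
#'   (recycled per site if a vector).
#' @return `read_sync()`: tibble with `chrom`, `pos`, `gen`, `rep`, `count`,
#'   `coverage`, `freq` (NaN where coverage is 0; the likelihood layer drops
#'   such entries).
#' @export
read_sync <- function(path, sample_map, derived_base = "T") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), pos = numeric(0), gen = integer(0),
                  rep = integer(0), count = integer(0), coverage = numeric(0),
                  freq = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_samp <- nrow(sample_map)
  bases <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  derived_base <- rep_len(derived_base, length(parts))
  rows <- vector("list", length(parts))
  last_pos <- -Inf; last_chrom <- ""
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 + n_samp) {
      abort(sprintf("malformed sync record at line %d: expected %d fields, got %d",
                    i, 3 + n_samp, length(p)))
    }
    pos <- suppressWarnings(as.numeric(p[2]))
    if (is.na(pos)) abort(sprintf("malformed position at line %d", i))
    if (p[1] == last_chrom && pos <= last_pos) {
      warn(sprintf("non-monotone position at line %d", i))
    }
    last_pos <- pos; last_chrom <- p[1]
    db <- bases[[derived_base[i]]]
    out <- matrix(NA_real_, n_samp, 2)
    for (s in seq_len(n_samp)) {
      sext <- suppressWarnings(
        as.numeric(strsplit(p[3 + sample_map$column[s]], ":", fixed = TRUE)[[1]]))
      if (length(sext) != 6 || anyNA(sext)) {
        abort(sprintf("malformed count sextet at line %d, sample %d", i, s))
      }
      if (any(sext < 0)) abort(sprintf("negative count at line %d", i))
      out[s, ] <- c(sext[db], sum(sext))
    }
    rows[[i]] <- tibble(chrom = p[1], pos = pos,
                        gen = as.integer(sample_map$gen),
                        rep = as.integer(sample_map$rep),
                        count = as.integer(out[, 1]), coverage = out[, 2])
  }
  out <- dplyr::bind_rows(rows)
  out$freq <- out$count / out$coverage
  out
}

#' @rdname read_sync
#' @param data long trajectory tibble with `pos`, `gen`, `rep`, `count`,
#'   `coverage` (integer counts required; refuse infinite-coverage data).
#' @param chrom chromosome label written to every record.
#' @param ancestral_base base receiving the non-derived reads.
#' @export
write_sync <- function(data, path, chrom = "chr1", derived_base = "T",
                       ancestral_base = "A") {
  if (nrow(data) > 0 && (any(is.infinite(data$coverage)) || anyNA(data$count))) {
    abort(paste("sync files store integer read counts; infinite-coverage",
                "(exact-frequency) data has none - use write_trajectories()"))
  }
  if (derived_base == ancestral_base) abort("derived and ancestral base must differ")
  samples <- dplyr::distinct(data[, c("gen", "rep")])
  samples <- samples[order(samples$gen, samples$rep), ]
  header <- paste("#chrom", "pos", "ref",
                  paste(sprintf("gen%d_rep%d", samples$gen, samples$rep),
                        collapse = "\t"), sep = "\t")
  sites <- sort(unique(data$pos))
  base_slot <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  lines <- character(length(sites))
  for (i in seq_along(sites)) {
    d <- data[data$pos == sites[i], ]
    fields <- vapply(seq_len(nrow(samples)), function(s) {
      row <- d[d$gen == samples$gen[s] & d$rep == samples$rep[s], ]
      sext <- integer(6)
      if (nrow(row) == 1) {
        sext[base_slot[[derived_base]]] <- row$count
        sext[base_slot[[ancestral_base]]] <- row$coverage - row$count
      }
      paste(sext, collapse = ":")
    }, character(1))
    lines[i] <- paste(chrom, sites[i], ancestral_base,
                      paste(fields, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Long-format trajectory TSV
#'
#' A simpler exchange format than sync: one row per (generation, replicate,
#' position) with count, coverage and frequency columns; handles
#' infinite-coverage (exact frequency) data that sync cannot.
#'
#' @param data long trajectory tibble.
#' @param path file path.
#' @return `read_trajectories()`: the tibble; `write_trajectories()`: the
#'   path, invisibly.
#' @export
write_trajectories <- function(data, path) {
  readr::write_tsv(data[, intersect(c("gen", "rep", "chrom", "pos", "count",
                                      "coverage", "freq"), names(data))],
                   path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write founder panels
#'
#' Tab-separated panel format: a comment line `#region_length=<bp>`, a
#' header row of positions, then one row per founder line holding its
#' haplotype as a string of 0/1 characters.  A FASTA-like variant
#' (`read_founders_fasta()` / `write_founders_fasta()`) stores one record
#' per founder with the 0/1 string as the sequence; positions travel in the
#' header of the first record.
#'
#' @param panel a [founder_panel()].
#' @param path file path.
#' @return `read_founders()`: a [founder_panel()] (invariants enforced).
#' @export
write_founders <- function(panel, path) {
  writeLines(c(
    sprintf("#region_length=%g", panel$region_length),
    paste(panel$positions, collapse = "\t"),
    apply(panel$haplotypes, 1, paste, collapse = "")
  ), path)
  invisible(path)
}

#' @rdname write_founders
#' @export
read_founders <- function(path) {
  lines <- readLines(path)
  region_length <- NA_real_
  if (startsWith(lines[1], "#region_length=")) {
    region_length <- as.numeric(sub("#region_length=", "", lines[1]))
    lines <- lines[-1]
  }
  positions <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (anyNA(positions)) abort("malformed position header")
  if (anyDuplicated(positions)) abort("duplicate positions in panel file")
  rows <- lines[-1]
  rows <- rows[nzchar(rows)]
  chars <- strsplit(rows, "")
  if (any(lengths(chars) != length(positions))) {
    abort("ragged founder matrix: row lengths do not match the position header")
  }
  m <- do.call(rbind, lapply(chars, function(ch) {
    if (!all(ch %in% c("0", "1"))) abort("non-binary character in founder haplotype")
    as.integer(ch)
  }))
  founder_panel(m, positions,
                region_length = if (is.na(region_length)) max(positions)
                                else region_length)
}

#' @rdname write_founders
#' @export
write_founders_fasta <- function(panel, path) {
  recs <- character(2 * nrow(panel$haplotypes))
  for (i in seq_len(nrow(panel$haplotypes))) {
    hdr <- if (i == 1) {
      sprintf(">founder_1 region_length=%g positions=%s",
              panel$region_length, paste(panel$positions, collapse = ","))
    } else sprintf(">founder_%d", i)
    recs[2 * i - 1] <- hdr
    recs[2 * i] <- paste(panel$haplotypes[i, ], collapse = "")
  }
  writeLines(recs, path)
  invisible(path)
}

#' @rdname write_founders
#' @export
read_founders_fasta <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0) abort("no FASTA records found")
  first <- lines[hdr_idx[1]]
  pos_str <- sub(".*positions=", "", first)
  positions <- as.numeric(strsplit(pos_str, ",", fixed = TRUE)[[1]])
  region_length <- as.numeric(sub(".*region_length=([0-9.e+]+).*", "\\1", first))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    from <- hdr_idx[i] + 1
    to <- if (i < length(hdr_idx)) hdr_idx[i + 1] - 1 else length(lines)
    paste(lines[from:to], collapse = "")
  }, character(1))
  m <- do.call(rbind, lapply(strsplit(seqs, ""), function(ch) {
    if (!all(ch %in% c("0", "1"))) abort("non-binary character in founder record")
    as.integer(ch)
  }))
  founder_panel(m, positions, region_length)
}

#' Write a scan/results table as TSV
#'
#' @param x a results tibble (e.g. from [lr_scan()] or [run_scan()]).
#' @param path file path.
#' @export
write_results <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read an empirical coverage-depth distribution
#'
#' Plain text, one non-negative integer depth per line (comments with `#`
#' allowed); the result feeds [coverage_empirical()].
#'
#' @param path file path.
#' @return integer vector of depths.
#' @export
read_depths <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(lines) & !startsWith(lines, "#")])
  d <- suppressWarnings(as.integer(lines))
  if (anyNA(d)) abort("depth file must contain one integer depth per line")
  if (any(d < 0)) abort("depths must be non-negative")
  d
}
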