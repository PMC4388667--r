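# Independent oracles used across the test suite.  All are brute-force or
# closed-form references implemented without any package internals.

# all haplotype-count states of M gametes over 4 two-locus haplotypes
enum_states4 <- function(M) {
  out <- list()
  for (a in 0:M) for (b in 0:(M - a)) for (cc in 0:(M - a - b)) {
    out[[length(out) + 1]] <- c(a, b, cc, M - a - b - cc)
  }
  do.call(rbind, out)
}

# exact moments of the neutral two-locus Wright-Fisher chain started from a
# representable point mass z0 (z0 * M integer), by powering the full
# transition matrix
exact_two_locus <- function(z0, r, M, t) {
  S <- enum_states4(M)
  ns <- nrow(S)
  P <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    z <- S[i, ] / M
    C <- z[1] * z[4] - z[2] * z[3]
    p <- z + r * C * c(-1, 1, 1, -1)
    p <- pmax(p, 0); p <- p / sum(p)
    P[i, ] <- apply(S, 1, function(s) dmultinom(s, M, p))
  }
  v <- rep(0, ns)
  v[which(apply(S, 1, function(s) all(abs(s - z0 * M) < 1e-9)))] <- 1
  for (u in seq_len(t)) v <- v %*% P
  v <- as.numeric(v)
  Z <- S / M
  list(mean = colSums(v * Z), second = t(Z) %*% (v * Z))
}

# exact moments of the one-locus selected Wright-Fisher chain (2N small)
exact_one_locus <- function(x0, s, h, n2, t) {
  states <- 0:n2 / n2
  f <- function(x) {
    x + s * x * (1 - x) * (h + (1 - 2 * h) * x) /
      (1 + s * x * (2 * h + (1 - 2 * h) * x))
  }
  P <- t(vapply(states, function(x) dbinom(0:n2, n2, f(x)), numeric(n2 + 1)))
  v <- rep(0, n2 + 1)
  v[which.min(abs(states - x0))] <- 1
  for (u in seq_len(t)) v <- v %*% P
  v <- as.numeric(v)
  list(mean = sum(v * states), second = sum(v * states^2),
       var = sum(v * states^2) - sum(v * states)^2)
}

# vectorised Monte-Carlo one-locus WF chain; returns nrun x length(at)
# matrix of frequencies at the requested generations
mc_one_locus <- function(x0, s, h, N, at, nrun) {
  n2 <- 2 * N
  x <- rep(x0, nrun)
  out <- matrix(NA_real_, nrun, length(at))
  f <- function(x) {
    x + s * x * (1 - x) * (h + (1 - 2 * h) * x) /
      (1 + s * x * (2 * h + (1 - 2 * h) * x))
  }
  for (t in seq_len(max(at))) {
    x <- rbinom(nrun, n2, f(x)) / n2
    j <- match(t, at)
    if (!is.na(j)) out[, j] <- x
  }
  out
}

# vectorised Monte-Carlo two-locus WF chain (optionally with selection at
# locus `selpos`); returns list of nrun x 4 haplotype-frequency matrices at
# the requested generations
mc_two_locus <- function(z0, r, N, at, nrun, s = 0, h = 0.5, selpos = 1) {
  n2 <- 2 * N
  Z <- matrix(rep(z0, each = nrun), nrun, 4)
  out <- vector("list", length(at))
  for (t in seq_len(max(at))) {
    p <- Z
    if (s != 0) {
      a <- if (selpos == 1) c(1, 1, 0, 0) else c(1, 0, 1, 0)
      x <- drop(Z %*% a)
      wc <- 1 + s * (h + (1 - h) * x)   # carrier marginal fitness
      wn <- 1 + s * h * x               # non-carrier
      W <- matrix(rep(wn, 4), nrun, 4)
      W[, a == 1] <- wc
      p <- Z * W / rowSums(Z * W)
    }
    C <- p[, 1] * p[, 4] - p[, 2] * p[, 3]
    p <- pmax(p + C %o% (r * c(-1, 1, 1, -1)), 0)
    p <- p / rowSums(p)
    n1 <- rbinom(nrun, n2, p[, 1])
    n2a <- rbinom(nrun, n2 - n1, pmin(pmax(p[, 2] / (1 - p[, 1]), 0), 1))
    n3 <- rbinom(nrun, n2 - n1 - n2a,
                 pmin(pmax(p[, 3] / pmax(1 - p[, 1] - p[, 2], 1e-12), 0), 1))
    Z <- cbind(n1, n2a, n3, n2 - n1 - n2a - n3) / n2
    j <- match(t, at)
    if (!is.na(j)) out[[j]] <- Z
  }
  out
}

# small founder panel with exact per-site allele counts
toy_panel <- function(counts, n_founders, positions = NULL,
                      region_length = NULL, seed = 1) {
  set.seed(seed)
  k <- length(counts)
  positions <- positions %||% ((1:k) * 100)
  haps <- matrix(0L, n_founders, k)
  for (j in seq_len(k)) haps[sample.int(n_founders, counts[j]), j] <- 1L
  founder_panel(haps, positions,
                region_length %||% (max(positions) + 100))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
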