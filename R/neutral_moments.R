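#' Two-locus neutral Wright-Fisher: initial state
#'
#' Haplotype order is (A1A1, A1A0, A0A1, A0A0); the linkage disequilibrium of
#' a frequency vector `z` is `C = z1 z4 - z2 z3` and the sign vector
#' `eps = (-1, 1, 1, -1)` gives the direction in which recombination moves
#' each haplotype class.
#'
#' @param z length-4 haplotype frequency vector on the simplex.
#' @param r recombination fraction between the two loci, in `[0, 0.5]`.
#' @param n_diploid diploid population size `N`.
#' @return an object of class `two_locus_init` with `z`, `c0`, `r`, `N`.
#' @export
two_locus_init <- function(z, r, n_diploid) {
  stopifnot(length(z) == 4, all(z >= -1e-12), abs(sum(z) - 1) < 1e-8,
            r >= 0, r <= 0.5, n_diploid >= 1)
  z <- pmax(z, 0) / sum(pmax(z, 0))
  structure(list(z = z, c0 = z[1] * z[4] - z[2] * z[3], r = r,
                 N = n_diploid),
            class = "two_locus_init")
}

.eps <- c(-1, 1, 1, -1)

# d_k in the LD-product moment: z1*z4 for the coupling classes (eps = -1),
# -z2*z3 for the repulsion classes (eps = +1)
.ld_d <- function(z) ifelse(.eps < 0, z[1] * z[4], -z[2] * z[3])

check_tr <- function(r, t) {
  if (r * max(t) >= 0.1) {
    warn(sprintf(
      "t * r = %.3g; the O(r + 1/2N) moment approximation degrades when t*r is not small",
      r * max(t)))
  }
}

#' First-order moments of the neutral two-locus process
#'
#' Closed-form approximations, accurate to `O(r + 1/(2N))`, for the
#' haplotype means, the `r`-scaled second moments and the `r`-scaled
#' LD-product moments after `t` generations of neutral Wright-Fisher
#' reproduction with recombination started from a known haplotype
#' configuration.
#'
#' @param init a [two_locus_init()].
#' @param t non-negative integer number of generations.
#' @return list with `means` (length 4), `r_products` (4 x 4 matrix, the
#'   moments `E(r Z_t^i Z_t^j)`) and `r_ld_products` (length 4, the moments
#'   `E(r Z_t^i C_t)`).
#' @export
neutral_hap_means <- function(init, t) {
  check_tr(init$r, t)
  z <- init$z; r <- init$r; c0 <- init$c0; N <- init$N
  means <- z + .eps * t * r * c0 * (1 - (t - 1) / (4 * N))
  r_products <- r / (2 * N) *
    (outer(z, z) * (2 * N - t) + t * diag(z, 4))
  r_ld_products <- r / (2 * N) * (z * c0 * (2 * N - 3 * t) +
                                    (t / 2) * ((1 - .eps) * z[1] * z[4] -
                                               (1 + .eps) * z[2] * z[3]))
  list(means = means, r_products = r_products,
       r_ld_products = r_ld_products)
}

# E(Z_t^j C_t) without the leading factor r (needed by the cross-generation
# covariance, where it is multiplied by u*r)
ld_product <- function(init, t) {
  z <- init$z; c0 <- init$c0; N <- init$N
  z * c0 * (1 - 3 * t / (2 * N)) + (t / (2 * N)) * .ld_d(z)
}

#' Second moments of the neutral two-locus process
#'
#' The 4 x 4 matrix `E(Z_t^i Z_t^j)` to order `O(r + 1/(2N))`, combining the
#' multinomial drift term with the recombination corrections obtained by
#' summing the one-generation moment recursion in closed form (the
#' first-order recursion is driven by the LD-product moments of
#' [neutral_hap_means()]).
#'
#' @inheritParams neutral_hap_means
#' @return symmetric 4 x 4 matrix of second moments.
#' @export
neutral_hap_second_moments <- function(init, t) {
  check_tr(init$r, t)
  z <- init$z; r <- init$r; c0 <- init$c0; N <- init$N
  d <- .ld_d(z)
  zz <- outer(z, z)
  et <- outer(.eps, z); eterm <- et + t(et)
  dt_ <- outer(.eps, d - 3 * z * c0); dterm <- dt_ + t(dt_)
  zz + (t / (2 * N)) * (diag(z, 4) - zz) +
    r * t * c0 * eterm +
    (r / (4 * N)) * (-c0 * eterm * t * (t + 1) + dterm * t * (t - 1)) +
    diag(r * .eps * c0 / (2 * N) * t * (t + 1) / 2, 4)
}

#' Cross-generation haplotype product moments
#'
#' `E(Z_{t+u}^i Z_t^j)` to order `O(r + 1/(2N))`, using the Markov property:
#' the conditional mean of `Z_{t+u}^i` given generation `t` is
#' `Z_t^i + eps_i u r C_t (1 - (u-1)/(4N))`, and the resulting products are
#' evaluated with the within-generation moments.
#'
#' @inheritParams neutral_hap_means
#' @param u lag in generations (>= 0).
#' @param i,j haplotype indices in 1..4 (optional; when missing the full
#'   4 x 4 matrix is returned).
#' @return single moment (when `i`, `j` given) or the 4 x 4 matrix with
#'   rows indexing the later generation.
#' @export
neutral_cross_moment <- function(init, t, u, i = NULL, j = NULL) {
  p <- neutral_hap_second_moments(init, t)
  q <- ld_product(init, t)
  fac <- u * init$r * (1 - (u - 1) / (4 * init$N))
  m <- p + fac * outer(.eps, q)
  if (is.null(i)) m else m[i, j]
}

#' Moments of the two marginal allele frequencies
#'
#' Transforms the haplotype moments into means, variances and within/cross
#' time covariances of the marginal derived-allele frequencies
#' `X^A = Z1 + Z2` and `X^B = Z1 + Z3` at the requested sampling times.
#' Under neutrality the marginal means are constant (the recombination terms
#' cancel in the marginal sums).
#'
#' @inheritParams neutral_hap_means
#' @param times strictly increasing positive sampling generations.
#' @return list with `means` (2-vector), `var` (T x 2 variances), and
#'   `cov` a 2T x 2T covariance matrix over the grid (time within locus A,
#'   then locus B).
#' @export
neutral_allele_moments <- function(init, times) {
  z <- init$z
  ia <- c(1, 2); ib <- c(1, 3)           # haplotypes carrying allele 1
  xa <- sum(z[ia]); xb <- sum(z[ib])
  tt <- length(times)
  means <- c(A = xa, B = xb)
  sets <- list(ia, ib)
  mean_of <- c(xa, xb)
  cv <- matrix(0, 2 * tt, 2 * tt)
  # one cross-moment matrix per (earlier time, lag) combination
  for (a in seq_len(tt)) for (b in seq_len(a)) {
    m <- neutral_cross_moment(init, times[b], times[a] - times[b])
    for (la in 1:2) for (lb in 1:2) {
      # rows of m index the later generation (time a)
      v <- sum(m[sets[[la]], sets[[lb]]]) - mean_of[la] * mean_of[lb]
      cv[(la - 1) * tt + a, (lb - 1) * tt + b] <- v
      cv[(lb - 1) * tt + b, (la - 1) * tt + a] <- v
    }
  }
  vars <- cbind(A = diag(cv)[seq_len(tt)], B = diag(cv)[tt + seq_len(tt)])
  list(means = means, var = vars, cov = cv, times = times)
}
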