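# Tajima's D: coefficients, the statistic, and its significance under a
# coalescent null conditional on the observed number of segregating sites
# (Hudson's fixed-S approach). The fixed-S null is self-consistent and
# fully seeded; the normalizing denominator is a function of (n, S) only,
# so null distributions are cached per (n, S, n_reps, seed).

#' Tajima (1989) normalizing coefficients
#'
#' The full coefficient set `a1, a2, b1, b2, c1, c2, e1, e2` used to
#' normalize the difference between the pairwise and Watterson estimators.
#' All coefficients are finite for `n >= 3`; for `n = 3` the variance
#' coefficients are exactly zero (pi and S/a1 coincide identically), so D
#' is undefined at that sample size.
#'
#' @param n Number of sequences (`n >= 3`).
#' @return Named list of the eight coefficients plus `n`.
#' @export
tajima_coefficients <- function(n) {
  if (n < 3) stop("tajima_coefficients requires n >= 3")
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D statistic
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Undefined (`NA`) when
#' `S = 0` (no variation) or when the variance term is zero (e.g. `n = 3`).
#' Negative values indicate an excess of rare variants relative to the
#' neutral equilibrium expectation; positive values an excess of
#' intermediate-frequency variants.
#'
#' @param S Number of segregating sites.
#' @param pi_locus Mean pairwise differences per locus.
#' @param n Number of sequences (`n >= 3`).
#' @return Numeric scalar, or `NA` when undefined.
#' @export
tajimas_d <- function(S, pi_locus, n) {
  if (n < 3) stop("tajimas_d requires n >= 3")
  if (S == 0) return(NA_real_)
  cf <- tajima_coefficients(n)
  v <- cf$e1 * S + cf$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_locus - S / cf$a1) / sqrt(v)
}

# Null distribution of D conditional on S: n_reps fixed-S coalescent
# replicates. Cached per (n, S, n_reps, seed); the cache makes repeated
# tests at the same sample size cheap.
tajima_null_distribution <- function(n, S, n_reps, seed) {
  key <- paste("tajnull", n, S, n_reps, seed, sep = "|")
  cache_get_or(key, function() {
    cf <- tajima_coefficients(n)
    denom <- sqrt(cf$e1 * S + cf$e2 * S * (S - 1))
    npairs <- n * (n - 1) / 2
    with_seed(seed, {
      d <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        tree <- sim_tree_onepop(n)
        idx <- sample.int(length(tree$blen), S, replace = TRUE,
                          prob = tree$blen)
        cc <- tree$bcnt[idx]
        pi_r <- sum(cc * (n - cc)) / npairs
        d[r] <- (pi_r - S / cf$a1) / denom
      }
      d
    })
  })
}

#' Significance of Tajima's D by fixed-S coalescent simulation
#'
#' Two-tailed p-value from the rank of `|D|` among `n_reps` neutral
#' coalescent replicates simulated conditional on the observed number of
#' segregating sites: `p = (1 + #{|D_sim| >= |D_obs|}) / (n_reps + 1)`.
#'
#' @param d_obs Observed D (finite).
#' @param n Number of sequences.
#' @param S Observed number of segregating sites (`>= 1`).
#' @param n_reps Number of null replicates (`>= 100`).
#' @param seed Integer seed (null replicates are reproducible and shared
#'   across tests with identical `(n, S, n_reps, seed)`).
#' @return Two-tailed p-value in (0, 1].
#' @export
tajima_significance <- function(d_obs, n, S, n_reps = 10000, seed) {
  if (n_reps < 100) stop("n_reps below 100 is rejected")
  if (missing(seed)) stop("tajima_significance requires a seed")
  if (!is.finite(d_obs)) stop("D must be defined to test significance")
  d_null <- tajima_null_distribution(n, S, n_reps, seed)
  (1 + sum(abs(d_null) >= abs(d_obs))) / (n_reps + 1)
}

#' Tajima's D test for one core alignment
#'
#' Computes S, pi and D on the core alignment and, when D is defined,
#' its fixed-S simulation p-value.
#'
#' @param core A `core_alignment`.
#' @param n_reps Null replicates for the significance simulation.
#' @param seed Integer seed.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return One-row data frame: `locus_id`, `n`, `S`, `pi_locus`, `D`, `p`,
#'   `significant`. `S = 0` yields undefined D, `p = NA` and
#'   `significant = FALSE`.
#' @export
tajima_test <- function(core, n_reps = 10000, seed, alpha = 0.05) {
  n <- nrow(core$seq)
  cat_ <- find_segregating_sites(core)
  pp <- pairwise_pi(core)
  d <- if (cat_$S > 0 && n >= 3) tajimas_d(cat_$S, pp$pi_locus, n) else NA_real_
  p <- NA_real_
  sig <- FALSE
  if (is.finite(d)) {
    p <- tajima_significance(d, n, cat_$S, n_reps = n_reps, seed = seed)
    sig <- p < alpha
  }
  data.frame(
    locus_id = core$locus_id, n = n, S = cat_$S,
    pi_locus = pp$pi_locus, D = d, p = p, significant = sig,
    stringsAsFactors = FALSE
  )
}

#' Histogram of Tajima's D values across loci
#'
#' Bins defined D values (default width 0.5, aligned on bin edges at
#' multiples of the width) and reports the mean and moment skewness.
#'
#' @param d_values Numeric vector of D values (NAs dropped).
#' @param bin_width Bin width (default 0.5).
#' @return List with `histogram` (data frame `bin_low`, `bin_high`,
#'   `count`), `mean`, `skewness`, `n`.
#' @export
d_distribution <- function(d_values, bin_width = 0.5) {
  d <- d_values[is.finite(d_values)]
  if (length(d) == 0) stop("no defined D values")
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cuts <- cut(d, breaks = breaks, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(cuts))
  m <- mean(d)
  s <- stats::sd(d)
  skew <- if (length(d) > 2 && s > 0) mean((d - m)^3) / s^3 else 0
  list(
    histogram = data.frame(
      bin_low = breaks[-length(breaks)],
      bin_high = breaks[-1],
      count = counts
    ),
    mean = m,
    skewness = skew,
    n = length(d)
  )
}
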