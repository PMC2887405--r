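# Multi-locus Hudson-Kreitman-Aguade test.
#
# Reduced formulation: one ingroup species' polymorphism plus net
# divergence to a single outgroup lineage (two sequenced outgroup
# accessions are averaged), without a second-species polymorphism term.
# Per-locus expectations under neutrality, with theta_i the per-locus
# population mutation rate and T the species divergence time in 2N units
# (ancestral population size equal to the current one):
#
#   E[S_i] = theta_i * a1(n_i)          Var[S_i] = E[S_i] + theta_i^2 * a2(n_i)
#   E[D_i] = theta_i * (T + 1)          Var[D_i] = E[D_i] + theta_i^2
#
# (The "+1" in E[D] and the theta^2 variance terms are the contribution of
# the coalescent time of the sampled pair in the ancestral population.)
# Method-of-moments estimation solves, for k loci and k + 1 parameters:
#
#   sum_i S_i = sum_i theta_i a1_i,  S_i + D_i = theta_i (a1_i + T + 1),
#
# which pins each theta_i given T and leaves one monotone equation in T.
# Polymorphism and divergence are both measured on the shared ingroup +
# outgroup gap-free core, so a single core length underlies both counts at
# each locus. Significance comes from parametric coalescent simulation of
# (S_i, D_i) at the fitted parameters with full re-estimation per
# simulated dataset.

#' Assemble one locus' HKA input
#'
#' @param locus_id Locus identifier.
#' @param n_ingroup Ingroup sample size (`>= 2`).
#' @param L Shared core length used for both polymorphism and divergence.
#' @param S_obs Observed segregating sites in the ingroup sample.
#' @param D_obs Observed mean pairwise ingroup-outgroup differences.
#' @param is_reference Whether this is a neutral reference locus.
#' @return One-row data frame of class `hka_locus_input`.
#' @export
hka_locus_input <- function(locus_id, n_ingroup, L, S_obs, D_obs,
                            is_reference = FALSE) {
  stopifnot(n_ingroup >= 2, L >= 0, S_obs >= 0, S_obs <= L, D_obs >= 0)
  out <- data.frame(
    locus_id = locus_id, n_ingroup = as.integer(n_ingroup), L = as.integer(L),
    S_obs = S_obs, D_obs = D_obs, is_reference = is_reference,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hka_locus_input", "data.frame")
  out
}

#' Compute HKA inputs from an aligned locus
#'
#' Builds the shared gap-free core over the ingroup plus outgroup
#' accessions, counts ingroup segregating sites on it, and measures
#' divergence as the mean pairwise difference between every ingroup and
#' every outgroup sequence on the same columns (no multiple-hit
#' correction).
#'
#' @param locus An `aligned_locus`.
#' @param ingroup Character vector of ingroup accession ids.
#' @param outgroup Character vector of outgroup accession ids (`>= 1`;
#'   several outgroup sequences are averaged).
#' @param is_reference Reference-locus flag, passed through.
#' @return An `hka_locus_input` row.
#' @export
hka_inputs_from_alignment <- function(locus, ingroup, outgroup,
                                      is_reference = FALSE) {
  stopifnot(length(ingroup) >= 2, length(outgroup) >= 1)
  core <- extract_core_alignment(locus, c(ingroup, outgroup))
  inmat <- core$seq[ingroup, , drop = FALSE]
  outmat <- core$seq[outgroup, , drop = FALSE]
  incore <- structure(
    list(locus_id = locus$locus_id, seq = inmat,
         kept_columns = core$kept_columns, L = core$L),
    class = "core_alignment"
  )
  S <- find_segregating_sites(incore)$S
  diffs <- 0
  for (i in seq_len(nrow(inmat))) {
    for (j in seq_len(nrow(outmat))) {
      diffs <- diffs + sum(inmat[i, ] != outmat[j, ])
    }
  }
  D <- diffs / (nrow(inmat) * nrow(outmat))
  hka_locus_input(locus$locus_id, nrow(inmat), core$L, S, D, is_reference)
}

# Lean fitting core shared by the public estimator and the simulation
# loop. S, D, a1, a2 are parallel vectors; returns theta (per locus), T,
# X2 and per-locus deviance components. Degenerate totals (all-zero S or
# all-zero D) are perfect fits in the limit: X2 = 0.
.hka_fit <- function(S, D, a1, a2, tol = 1e-10) {
  tot_S <- sum(S)
  tot_D <- sum(D)
  if (tot_S + tot_D == 0) {
    stop("all-zero HKA data: no polymorphism and no divergence")
  }
  if (tot_S == 0 || tot_D == 0) {
    # boundary of the parameter space (T -> Inf or T -> -1): expectations
    # match observations exactly in the limit
    k <- length(S)
    return(list(
      theta = (S + D) / a1, T = NA_real_, X2 = 0,
      dev_poly = numeric(k), dev_div = numeric(k),
      E_S = S, E_D = D, degenerate = TRUE, converged = TRUE
    ))
  }
  if (length(unique(a1)) == 1L) {
    # equal sample sizes (and the saturated one-locus case): closed form
    T_hat <- a1[1] * tot_D / tot_S - 1
  } else {
    g <- function(T) sum((S + D) * a1 / (a1 + T + 1)) - tot_S
    upper <- 10
    while (g(upper) > 0 && upper < 1e12) upper <- upper * 10
    root <- stats::uniroot(g, lower = -1 + 1e-9, upper = upper, tol = tol)
    T_hat <- root$root
  }
  theta <- (S + D) / (a1 + T_hat + 1)
  E_S <- theta * a1
  E_D <- theta * (T_hat + 1)
  V_S <- E_S + theta^2 * a2
  V_D <- E_D + theta^2
  dev_poly <- ifelse(V_S > 0, (S - E_S)^2 / V_S, ifelse(S == E_S, 0, NA_real_))
  dev_div <- ifelse(V_D > 0, (D - E_D)^2 / V_D, ifelse(D == E_D, 0, NA_real_))
  if (anyNA(dev_poly) || anyNA(dev_div)) {
    stop("zero variance with non-zero deviation in HKA fit")
  }
  list(
    theta = theta, T = T_hat, X2 = sum(dev_poly) + sum(dev_div),
    dev_poly = dev_poly, dev_div = dev_div,
    E_S = E_S, E_D = E_D, degenerate = FALSE, converged = TRUE
  )
}

#' Estimate the multi-locus HKA parameters
#'
#' Method-of-moments fit of per-locus `theta_i` and the common divergence
#' time `T`, constrained so that expected and observed totals match
#' (`sum E[S_i] = sum S_i`, `sum E[D_i] = sum D_i`, and per-locus
#' `S_i + D_i` are reproduced exactly). The single free equation in `T` is
#' monotone and solved numerically to tolerance `1e-10`.
#'
#' @param inputs Data frame of stacked [hka_locus_input()] rows (`>= 1`).
#' @return An `hka_fit`: list with `inputs`, `theta` (per-locus), `T_hat`,
#'   `X2`, `dev_poly`, `dev_div`, `E_S`, `E_D`, `degenerate`.
#' @export
estimate_hka_parameters <- function(inputs) {
  stopifnot(nrow(inputs) >= 1)
  a1 <- vapply(inputs$n_ingroup, harmonic_a1, numeric(1))
  a2 <- vapply(inputs$n_ingroup, harmonic_a2, numeric(1))
  fit <- .hka_fit(inputs$S_obs, inputs$D_obs, a1, a2)
  structure(
    list(
      inputs = inputs, theta = fit$theta, T_hat = fit$T, X2 = fit$X2,
      dev_poly = fit$dev_poly, dev_div = fit$dev_div,
      E_S = fit$E_S, E_D = fit$E_D, degenerate = fit$degenerate
    ),
    class = "hka_fit"
  )
}

#' Goodness-of-fit statistic of an HKA fit
#'
#' `X2 = sum_i (S_i - E[S_i])^2 / Var[S_i] + (D_i - E[D_i])^2 / Var[D_i]`;
#' exactly 0 for the saturated one-locus fit.
#'
#' @param fit An `hka_fit` from [estimate_hka_parameters()].
#' @return Numeric scalar `X2 >= 0`.
#' @export
hka_statistic <- function(fit) {
  stopifnot(inherits(fit, "hka_fit"))
  fit$X2
}

# Simulate one dataset of (S_i, D_i) at fitted parameters. theta per
# locus, common T; structured genealogy per locus with one outgroup
# lineage.
.hka_simulate_dataset <- function(theta, T_hat, n_ingroup) {
  k <- length(theta)
  S <- numeric(k)
  D <- numeric(k)
  for (i in seq_len(k)) {
    tree <- sim_tree_split(n_ingroup[i], T_hat)
    tot <- sum(tree$blen)
    nmut <- stats::rpois(1L, theta[i] / 2 * tot)
    if (nmut > 0L) {
      idx <- sample.int(length(tree$blen), nmut, replace = TRUE,
                        prob = tree$blen)
      cc <- tree$bcnt[idx]
      oo <- tree$bout[idx]
      n <- n_ingroup[i]
      S[i] <- sum(cc > 0L & cc < n)
      D[i] <- sum(ifelse(oo > 0L, n - cc, cc)) / n
    }
  }
  list(S = S, D = D)
}

#' HKA test of a candidate locus against neutral references
#'
#' Fits the multi-locus HKA model on the candidate plus the reference
#' loci, then simulates `n_sim` datasets of `(S_i, D_i)` under the fitted
#' neutral parameters (coalescent genealogies with the fitted divergence
#' time, Poisson mutations), re-estimating the model on each to obtain the
#' null distribution of `X2`. `p = (1 + #{X2_sim >= X2_obs}) / (n_sim + 1)`.
#'
#' @param candidate An `hka_locus_input` row with
#'   `is_reference = FALSE`.
#' @param references Stacked `hka_locus_input` rows (`>= 1`).
#' @param n_sim Number of parametric simulations (default 10000).
#' @param seed Integer seed (mandatory).
#' @param alpha Significance level (default 0.05).
#' @return One-row data frame (class `hka_result`): `locus_id`, `X2`,
#'   `p`, `n_sim`, `significant`, `T_hat`.
#' @export
hka_candidate_test <- function(candidate, references, n_sim = 10000, seed,
                               alpha = 0.05) {
  if (missing(seed)) stop("hka_candidate_test requires a seed")
  stopifnot(nrow(candidate) == 1, !candidate$is_reference, nrow(references) >= 1)
  inputs <- rbind(candidate, references)
  if (anyDuplicated(inputs$locus_id)) {
    stop("duplicate locus ids in HKA inputs")
  }
  # canonical locus order so the simulated null (and hence p) does not
  # depend on how the references were passed in
  inputs <- inputs[order(inputs$locus_id), , drop = FALSE]
  fit <- estimate_hka_parameters(inputs)
  x2_obs <- hka_statistic(fit)
  a1 <- vapply(inputs$n_ingroup, harmonic_a1, numeric(1))
  a2 <- vapply(inputs$n_ingroup, harmonic_a2, numeric(1))
  exceed <- 0L
  if (fit$degenerate) {
    # no information to simulate against; report non-significant p = 1
    p <- 1
  } else {
    with_seed(seed, {
      for (s in seq_len(n_sim)) {
        sim <- .hka_simulate_dataset(fit$theta, fit$T_hat, inputs$n_ingroup)
        if (sum(sim$S) + sum(sim$D) == 0) {
          x2_sim <- 0
        } else {
          x2_sim <- .hka_fit(sim$S, sim$D, a1, a2)$X2
        }
        if (x2_sim >= x2_obs) exceed <- exceed + 1L
      }
    })
    p <- (1 + exceed) / (n_sim + 1)
  }
  out <- data.frame(
    locus_id = candidate$locus_id, X2 = x2_obs, p = p,
    n_sim = as.integer(n_sim), significant = p < alpha,
    T_hat = fit$T_hat, stringsAsFactors = FALSE
  )
  class(out) <- c("hka_result", "data.frame")
  out
}
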