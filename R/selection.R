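# Fold-reduction screening against the neutral-gene baseline and the
# domestication-candidate classification.
#
# A "positive selection signal" in a population is a significantly
# NEGATIVE Tajima's D or an HKA p-value below alpha; a significantly
# positive D (balancing selection) is not a selection signal. A locus is a
# putative domestication candidate when a cultivated subgroup shows a
# signal and the wild population shows none. The fold-reduction screen
# (wild/cultivated per-site pi against the maximum reduction among neutral
# reference genes) is reported independently, as a separate line of
# evidence.

#' Baseline fold reduction from neutral reference loci
#'
#' The screen threshold is the maximum fold reduction observed at the
#' neutral reference loci; undefined (non-finite) folds are dropped with a
#' warning.
#'
#' @param neutral_folds Numeric vector of reference-locus fold reductions.
#' @return The maximum defined fold.
#' @export
neutral_baseline <- function(neutral_folds) {
  if (length(neutral_folds) == 0) stop("no neutral fold values")
  keep <- is.finite(neutral_folds)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " undefined neutral fold value(s)")
  }
  if (!any(keep)) stop("no defined neutral fold values")
  max(neutral_folds[keep])
}

#' Fold reduction of cultivated relative to wild diversity
#'
#' `fold = pi_wild / pi_cult` (per-site values). A cultivated diversity of
#' zero with positive wild diversity gives `Inf` (flagged as exceeding any
#' baseline); both zero is undefined (`NA`, excluded from the screen).
#'
#' @param pi_wild,pi_cult Per-site pi of the wild and cultivated samples.
#' @param baseline Neutral baseline from [neutral_baseline()].
#' @return One-row data frame: `pi_wild_site`, `pi_cult_site`, `fold`,
#'   `exceeds_baseline`.
#' @export
fold_reduction <- function(pi_wild, pi_cult, baseline) {
  stopifnot(pi_wild >= 0 || is.na(pi_wild), pi_cult >= 0 || is.na(pi_cult))
  if (is.na(pi_wild) || is.na(pi_cult) || (pi_wild == 0 && pi_cult == 0)) {
    fold <- NA_real_
    exceeds <- NA
  } else if (pi_cult == 0) {
    fold <- Inf
    exceeds <- TRUE
  } else {
    fold <- pi_wild / pi_cult
    exceeds <- fold > baseline
  }
  data.frame(
    pi_wild_site = pi_wild, pi_cult_site = pi_cult,
    fold = fold, exceeds_baseline = exceeds
  )
}

# One population's signal: significant negative D OR HKA p < alpha.
# Missing tests count as no-signal for that test only.
.population_signal <- function(d, d_significant, hka_p, alpha = 0.05) {
  d_sig <- isTRUE(d_significant) && is.finite(d) && d < 0
  hka_sig <- is.finite(hka_p) && hka_p < alpha
  d_sig || hka_sig
}

#' Classify one locus as a domestication-selection candidate
#'
#' Applies the candidate rule: `Putative` iff a positive-selection signal
#' (significant negative Tajima's D or HKA `p < alpha`) is present in at
#' least one cultivated subgroup AND absent from the wild population;
#' `ND` (not detected) when tests are available but the rule is not met;
#' `NA` when the required tests are missing in both cultivated subgroups.
#'
#' @param d_indica,d_japonica,d_wild Tajima's D values (NA when
#'   undefined/untested).
#' @param sig_indica,sig_japonica,sig_wild Logical: two-tailed D
#'   significance flags.
#' @param hka_indica,hka_japonica,hka_wild HKA p-values (NA when
#'   untested).
#' @param alpha Significance level (default 0.05).
#' @return One-row data frame: `signal_indica`, `signal_japonica`,
#'   `signal_wild`, `status` (`"Putative"`, `"ND"` or `"NA"`).
#' @export
classify_candidate <- function(d_indica = NA, sig_indica = NA, hka_indica = NA,
                               d_japonica = NA, sig_japonica = NA,
                               hka_japonica = NA,
                               d_wild = NA, sig_wild = NA, hka_wild = NA,
                               alpha = 0.05) {
  ind_has <- is.finite(d_indica) || is.finite(hka_indica)
  jap_has <- is.finite(d_japonica) || is.finite(hka_japonica)
  s_ind <- .population_signal(d_indica, sig_indica, hka_indica, alpha)
  s_jap <- .population_signal(d_japonica, sig_japonica, hka_japonica, alpha)
  s_wild <- .population_signal(d_wild, sig_wild, hka_wild, alpha)
  status <- if (!ind_has && !jap_has) {
    "NA"
  } else if ((s_ind || s_jap) && !s_wild) {
    "Putative"
  } else {
    "ND"
  }
  data.frame(
    signal_indica = s_ind, signal_japonica = s_jap, signal_wild = s_wild,
    status = status, stringsAsFactors = FALSE
  )
}

#' Build the per-locus selection report table
#'
#' Joins per-subgroup Tajima and HKA results into one row per locus with
#' sample sizes, D, HKA p-values, the candidate status, and (when
#' diversity values are supplied) the wild/cultivated fold reductions.
#'
#' @param tests Data frame with one row per (locus, population) holding
#'   columns `locus_id`, `group` (`indica`/`japonica`/`wild`), `n`, `D`,
#'   `significant`, `hka_p`; missing combinations are treated as untested.
#' @param target_family Optional named character vector
#'   (locus_id -> annotation string) passed through to the report.
#' @param alpha Significance level.
#' @return Data frame with one row per locus (Table-style report):
#'   `locus_id`, per-group `n`/`D`/`hka_p`, `target_family`, `status`.
#' @export
build_selection_table <- function(tests, target_family = NULL, alpha = 0.05) {
  if (nrow(tests) == 0) {
    return(data.frame(
      locus_id = character(0), n_indica = integer(0), d_indica = numeric(0),
      hka_p_indica = numeric(0), n_japonica = integer(0),
      d_japonica = numeric(0), hka_p_japonica = numeric(0),
      n_wild = integer(0), d_wild = numeric(0), hka_p_wild = numeric(0),
      target_family = character(0), status = character(0),
      stringsAsFactors = FALSE
    ))
  }
  pick <- function(sub, group, col) {
    v <- sub[[col]][sub$group == group]
    if (length(v) == 0) NA else v[1]
  }
  rows <- lapply(split(tests, tests$locus_id), function(sub) {
    cls <- classify_candidate(
      d_indica = pick(sub, "indica", "D"),
      sig_indica = pick(sub, "indica", "significant"),
      hka_indica = pick(sub, "indica", "hka_p"),
      d_japonica = pick(sub, "japonica", "D"),
      sig_japonica = pick(sub, "japonica", "significant"),
      hka_japonica = pick(sub, "japonica", "hka_p"),
      d_wild = pick(sub, "wild", "D"),
      sig_wild = pick(sub, "wild", "significant"),
      hka_wild = pick(sub, "wild", "hka_p"),
      alpha = alpha
    )
    id <- sub$locus_id[1]
    data.frame(
      locus_id = id,
      n_indica = pick(sub, "indica", "n"),
      d_indica = pick(sub, "indica", "D"),
      hka_p_indica = pick(sub, "indica", "hka_p"),
      n_japonica = pick(sub, "japonica", "n"),
      d_japonica = pick(sub, "japonica", "D"),
      hka_p_japonica = pick(sub, "japonica", "hka_p"),
      n_wild = pick(sub, "wild", "n"),
      d_wild = pick(sub, "wild", "D"),
      hka_p_wild = pick(sub, "wild", "hka_p"),
      target_family = if (!is.null(target_family) && id %in% names(target_family))
        target_family[[id]] else NA_character_,
      status = cls$status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$status, c("Putative", "ND", "NA")), out$locus_id), ,
      drop = FALSE]
}
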