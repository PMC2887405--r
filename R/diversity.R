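# Segregating-site identification and the classical diversity estimators
# (Watterson's theta from S, pairwise pi), per locus, per annotated region
# and aggregated across loci.
#
# All diversity statistics are SNP-based on the gap-free core: indels never
# count toward S, pi or theta. Maximal runs of gapped columns on the
# original alignment are catalogued separately as single indel events for
# the mutation-catalogue module. Multi-allelic columns count as one
# segregating site.

# 4 x L matrix of allele counts over A/C/G/T for a character matrix.
allele_count_matrix <- function(mat) {
  if (ncol(mat) == 0) {
    return(matrix(0L, nrow = 4, ncol = 0, dimnames = list(VALID_BASES, NULL)))
  }
  counts <- vapply(
    VALID_BASES,
    function(b) colSums(mat == b),
    numeric(ncol(mat))
  )
  t(matrix(counts, ncol = 4, dimnames = list(NULL, VALID_BASES)))
}

#' Identify segregating sites and indel events
#'
#' A core column is segregating iff at least two distinct bases occur among
#' the analysed sequences. Indel events are detected on the original
#' alignment as maximal runs of columns containing a gap in any retained
#' sequence; they are catalogued but excluded from all diversity statistics.
#'
#' @param core A `core_alignment` (from [extract_core_alignment()]).
#' @param locus Optional originating `aligned_locus`; when supplied, indel
#'   events are detected on its columns restricted to the core's accessions.
#' @return A `site_catalog`: list with `locus_id`, `n`, `S`, `sites`
#'   (data frame: `core_position`, `alignment_position`, `alleles` as a
#'   comma-separated `base:count` string, `n_alleles`), `counts` (4 x S
#'   allele-count matrix) and `indels` (data frame `start`, `end`, `length`,
#'   `n_gapped` in alignment coordinates).
#' @export
find_segregating_sites <- function(core, locus = NULL) {
  if (nrow(core$seq) < 2) stop("need >= 2 sequences to find segregating sites")
  counts <- allele_count_matrix(core$seq)
  seg <- which(colSums(counts > 0) >= 2)
  site_counts <- counts[, seg, drop = FALSE]
  alleles <- vapply(seq_along(seg), function(k) {
    cc <- site_counts[, k]
    paste(sprintf("%s:%d", VALID_BASES[cc > 0], cc[cc > 0]), collapse = ",")
  }, character(1))
  sites <- data.frame(
    core_position = seg,
    alignment_position = core$kept_columns[seg],
    alleles = alleles,
    n_alleles = colSums(site_counts > 0),
    stringsAsFactors = FALSE
  )
  indels <- data.frame(
    start = integer(0), end = integer(0),
    length = integer(0), n_gapped = integer(0)
  )
  if (!is.null(locus)) {
    mat <- locus$seq[rownames(core$seq), , drop = FALSE]
    gapped <- colSums(mat == "-") > 0
    if (any(gapped)) {
      r <- rle(gapped)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      gi <- which(r$values)
      indels <- data.frame(
        start = starts[gi],
        end = ends[gi],
        length = r$lengths[gi],
        n_gapped = vapply(gi, function(k) {
          sum(rowSums(mat[, starts[k]:ends[k], drop = FALSE] == "-") > 0)
        }, numeric(1))
      )
    }
  }
  structure(
    list(
      locus_id = core$locus_id,
      n = nrow(core$seq),
      S = length(seg),
      sites = sites,
      counts = site_counts,
      indels = indels
    ),
    class = "site_catalog"
  )
}

#' Watterson's theta per locus
#'
#' `theta_W = S / a1(n)` with `a1(n)` the (n-1)-th partial harmonic sum;
#' estimates the per-locus population mutation rate from the number of
#' segregating sites.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (`n >= 2`).
#' @return Per-locus Watterson estimate (divide by core length for the
#'   per-site value).
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) stop("watterson_theta requires n >= 2")
  stopifnot(S >= 0)
  S / harmonic_a1(n)
}

#' Pairwise nucleotide diversity (pi)
#'
#' Mean number of differing core sites over all `n(n-1)/2` unordered pairs
#' of sequences (the per-locus `k-hat`); computed from per-column allele
#' counts, which is algebraically identical to the brute-force pairwise
#' recount.
#'
#' @param core A `core_alignment` with at least two sequences.
#' @return List with `pi_locus` (mean pairwise differences) and `pi_site`
#'   (`pi_locus / L`; `NA` when `L = 0`).
#' @export
pairwise_pi <- function(core) {
  n <- nrow(core$seq)
  if (n < 2) stop("pairwise_pi requires >= 2 sequences")
  if (core$L == 0) {
    return(list(pi_locus = NA_real_, pi_site = NA_real_))
  }
  counts <- allele_count_matrix(core$seq)
  npairs <- n * (n - 1) / 2
  same <- colSums(counts * (counts - 1) / 2)
  pi_locus <- sum(npairs - same) / npairs
  list(pi_locus = pi_locus, pi_site = pi_locus / core$L)
}

#' Per-locus diversity summary
#'
#' Bundles `n`, `L`, `S`, per-locus and per-site Watterson's theta and pi,
#' and the SNP density per kb for one core alignment.
#'
#' @param core A `core_alignment`.
#' @return A one-row data frame (class `diversity_stats`): `locus_id`, `n`,
#'   `L`, `S`, `theta_w_locus`, `pi_locus`, `theta_w_site`, `pi_site`,
#'   `snp_per_kb`.
#' @export
diversity_stats <- function(core) {
  n <- nrow(core$seq)
  cat_ <- find_segregating_sites(core)
  S <- cat_$S
  theta <- watterson_theta(S, n)
  pp <- pairwise_pi(core)
  out <- data.frame(
    locus_id = core$locus_id,
    n = n,
    L = core$L,
    S = S,
    theta_w_locus = theta,
    pi_locus = pp$pi_locus,
    theta_w_site = if (core$L > 0) theta / core$L else NA_real_,
    pi_site = pp$pi_site,
    snp_per_kb = if (core$L > 0) 1000 * S / core$L else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("diversity_stats", "data.frame")
  out
}

#' Region-partitioned diversity for one locus
#'
#' Recomputes the core alignment on the requested accession subset, maps
#' each annotated region into the surviving core columns and computes
#' diversity statistics on the restriction. Regions entirely lost from the
#' core yield `NA` statistics with a flag.
#'
#' @param locus An `aligned_locus`.
#' @param annotation A `locus_annotation` (rows for this locus are used).
#' @param subset Accession ids to analyse (default: all).
#' @return Data frame with one row per region (`region` = `label`/`name`)
#'   plus a `whole_locus` row; columns as [diversity_stats()] plus
#'   `region`, `name`, `region_core_length`.
#' @export
region_diversity <- function(locus, annotation, subset = NULL) {
  core <- extract_core_alignment(locus, subset)
  ann <- annotation[annotation$locus_id == locus$locus_id, , drop = FALSE]
  rows <- list()
  whole <- diversity_stats(core)
  whole$region <- "whole_locus"
  whole$name <- "whole_locus"
  whole$region_core_length <- core$L
  rows[["whole_locus"]] <- whole
  for (i in seq_len(nrow(ann))) {
    idx <- map_region_to_core(core, ann$start[i], ann$end[i])
    key <- paste(ann$label[i], ann$name[i], sep = "|")
    if (length(idx) == 0) {
      row <- data.frame(
        locus_id = locus$locus_id, n = nrow(core$seq), L = 0L, S = NA_integer_,
        theta_w_locus = NA_real_, pi_locus = NA_real_,
        theta_w_site = NA_real_, pi_site = NA_real_, snp_per_kb = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      sub <- structure(
        list(
          locus_id = locus$locus_id,
          seq = core$seq[, idx, drop = FALSE],
          kept_columns = core$kept_columns[idx],
          L = length(idx)
        ),
        class = "core_alignment"
      )
      row <- diversity_stats(sub)
    }
    row$region <- ann$label[i]
    row$name <- ann$name[i]
    row$region_core_length <- length(idx)
    rows[[key]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-locus diversity across loci
#'
#' Mean and standard error of the mean of a per-site statistic across loci,
#' grouped by arbitrary columns (region, conservation class, subgroup).
#' The SEM of a single-locus group is 0 so report tables stay total.
#'
#' @param df Data frame of per-locus values (e.g. stacked
#'   [region_diversity()] outputs with added grouping columns).
#' @param group_by Character vector of grouping column names.
#' @param stat Column to aggregate (default `"pi_site"`).
#' @return Data frame with the grouping columns plus `mean`, `sem`,
#'   `n_loci`.
#' @export
aggregate_diversity <- function(df, group_by, stat = "pi_site") {
  stopifnot(all(group_by %in% names(df)), stat %in% names(df))
  df <- df[!is.na(df[[stat]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no non-missing values to aggregate")
  key <- interaction(df[group_by], drop = TRUE, sep = "\r")
  agg <- lapply(split(df, key), function(sub) {
    vals <- sub[[stat]]
    sem <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0
    cbind(
      sub[1, group_by, drop = FALSE],
      data.frame(mean = mean(vals), sem = sem, n_loci = length(vals))
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
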