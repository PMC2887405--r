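# Catalogue of SNPs/indels inside annotated functional regions (mature
# miRNAs, ta-siRNA phases, miR390 binding sites) with per-population
# allele counts, and a penalty-scored miRNA:target-site scanner.
#
# Report positions are 1-based counting from the 5' end of the annotated
# region (alignments are stored on the precursor's plus strand, so region
# orientation matches alignment orientation). T and U are treated as
# identical everywhere.

#' Catalogue mutations in annotated functional regions
#'
#' Every segregating site and every indel event overlapping an annotated
#' region becomes one record (per region it overlaps), with allele counts
#' stratified by population and, within cultivated samples, by subgroup.
#'
#' @param locus An `aligned_locus`.
#' @param annotation A `locus_annotation` (rows for this locus are used).
#' @param panel A `population_panel` resolving every analysed accession.
#' @param subset Accessions to analyse (default: all in the locus).
#' @return A `mutation_catalog`: data frame with one row per record
#'   (`locus_id`, `region`, `name`, `mutation_type`, `position_in_region`,
#'   `alignment_position`, `length`, `alleles`), with a `counts` attribute
#'   (list of allele-by-group count matrices, one per record).
#' @export
catalog_region_mutations <- function(locus, annotation, panel, subset = NULL) {
  if (is.null(subset)) subset <- accessions(locus)
  check_panel_covers(locus, panel)
  core <- extract_core_alignment(locus, subset)
  cat_ <- find_segregating_sites(core, locus)
  ann <- annotation[annotation$locus_id == locus$locus_id, , drop = FALSE]
  pan <- panel[match(subset, panel$accession_id), ]
  group <- ifelse(
    pan$population == "cultivated", pan$subgroup, pan$population
  )
  groups <- intersect(c("indica", "japonica", "wild", "outgroup"),
                      unique(group))
  rows <- list()
  counts <- list()
  count_matrix <- function(chars) {
    tab <- table(
      factor(chars, levels = c(VALID_BASES, "-", "N")),
      factor(group, levels = groups)
    )
    m <- as.matrix(tab)
    m[rowSums(m) > 0, , drop = FALSE]
  }
  for (ri in seq_len(nrow(ann))) {
    r <- ann[ri, ]
    # SNPs
    in_region <- which(cat_$sites$alignment_position >= r$start &
                         cat_$sites$alignment_position <= r$end)
    for (si in in_region) {
      p <- cat_$sites$alignment_position[si]
      id <- sprintf("%s|%s|%s|SNP@%d", locus$locus_id, r$label, r$name, p)
      chars <- locus$seq[subset, p]
      rows[[id]] <- data.frame(
        locus_id = locus$locus_id, region = r$label, name = r$name,
        mutation_type = "SNP",
        position_in_region = p - r$start + 1L,
        alignment_position = p, length = 1L,
        alleles = cat_$sites$alleles[si],
        stringsAsFactors = FALSE
      )
      counts[[id]] <- count_matrix(chars)
    }
    # indel events (maximal gap runs on the original alignment)
    if (nrow(cat_$indels)) {
      ov <- which(cat_$indels$start <= r$end & cat_$indels$end >= r$start)
      for (ii in ov) {
        ev <- cat_$indels[ii, ]
        id <- sprintf("%s|%s|%s|indel@%d", locus$locus_id, r$label, r$name,
                      ev$start)
        has_gap <- rowSums(
          locus$seq[subset, ev$start:ev$end, drop = FALSE] == "-"
        ) > 0
        chars <- ifelse(has_gap, "-", "A") # presence/absence coding
        m <- table(
          factor(ifelse(has_gap, "deletion", "reference"),
                 levels = c("reference", "deletion")),
          factor(group, levels = groups)
        )
        rows[[id]] <- data.frame(
          locus_id = locus$locus_id, region = r$label, name = r$name,
          mutation_type = "indel",
          position_in_region = max(ev$start, r$start) - r$start + 1L,
          alignment_position = ev$start, length = ev$length,
          alleles = sprintf("deletion:%d,reference:%d",
                            sum(has_gap), sum(!has_gap)),
          stringsAsFactors = FALSE
        )
        counts[[id]] <- as.matrix(m)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    locus_id = character(0), region = character(0), name = character(0),
    mutation_type = character(0), position_in_region = integer(0),
    alignment_position = integer(0), length = integer(0),
    alleles = character(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  attr(out, "record_ids") <- names(rows)
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Per-population allele percentages for one catalogued mutation
#'
#' Converts one record's allele-by-group counts into percentages per
#' group; groups with zero analysed sequences are omitted. Percentages in
#' each group sum to 100 up to rounding.
#'
#' @param catalog A `mutation_catalog`.
#' @param record Record index (row number) or record id.
#' @return Data frame: `group`, `allele`, `count`, `percent`.
#' @export
allele_frequencies_by_population <- function(catalog, record = 1L) {
  counts <- attr(catalog, "counts")
  ids <- attr(catalog, "record_ids")
  m <- if (is.character(record)) counts[[record]] else counts[[ids[record]]]
  if (is.null(m)) stop("no such record")
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  rows <- list()
  for (g in colnames(m)) {
    tot <- sum(m[, g])
    rows[[g]] <- data.frame(
      group = g, allele = rownames(m), count = as.integer(m[, g]),
      percent = 100 * m[, g] / tot, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# penalty for one miRNA base (5'->3') against one site base, antiparallel:
# 0 Watson-Crick, `wobble` for G:U, `mismatch` otherwise. U == T.
.pair_penalty <- function(m, t, mismatch = 1, wobble = 0.5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(
    t == comp[m], 0,
    ifelse((m == "G" & t == "T") | (m == "T" & t == "G"), wobble, mismatch)
  )
}

#' Penalty score of a miRNA against a candidate target site
#'
#' Both sequences 5'->3', equal length, paired antiparallel (miRNA
#' position i against site position L - i + 1). Position penalties are 0
#' for a Watson-Crick pair, `wobble` (default 0.5) for a G:U pair and
#' `mismatch` (default 1) otherwise; the score is their sum. No
#' gaps/bulges are considered.
#'
#' @param mirna Mature miRNA sequence (A/C/G/U or T).
#' @param site Candidate target site, same length.
#' @param mismatch,wobble Penalty weights.
#' @return Numeric penalty score.
#' @export
target_penalty_score <- function(mirna, site, mismatch = 1, wobble = 0.5) {
  m <- strsplit(toupper(gsub("U", "T", mirna, ignore.case = TRUE)), "")[[1]]
  s <- strsplit(toupper(gsub("U", "T", site, ignore.case = TRUE)), "")[[1]]
  if (length(m) != length(s)) stop("miRNA and site must have equal lengths")
  sum(.pair_penalty(m, rev(s), mismatch, wobble))
}

#' Scan transcripts for miRNA target sites
#'
#' Slides a window of mature-miRNA length over each transcript, scoring
#' every window with [target_penalty_score()], and reports all hits with
#' penalty at or below `max_penalty`, sorted by penalty then coordinates.
#'
#' @param mirna Mature miRNA sequence (5'->3').
#' @param transcripts Named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param max_penalty Maximum reported penalty (default 4).
#' @param mismatch,wobble Penalty weights.
#' @param mirna_id Identifier carried into the report.
#' @return Data frame: `mirna_id`, `transcript_id`, `site_start` (1-based),
#'   `site_end`, `penalty`, `site`, `pairing` (`|` Watson-Crick, `o` G:U
#'   wobble, `.` mismatch, written 5'->3' of the miRNA).
#' @export
scan_targets <- function(mirna, transcripts, max_penalty = 4,
                         mismatch = 1, wobble = 0.5, mirna_id = "miRNA") {
  if (methods::is(transcripts, "XStringSet")) {
    transcripts <- as.character(transcripts)
  }
  if (length(transcripts) == 0) stop("no transcripts to scan")
  if (is.null(names(transcripts))) {
    names(transcripts) <- sprintf("transcript%02d", seq_along(transcripts))
  }
  m <- strsplit(toupper(gsub("U", "T", mirna, ignore.case = TRUE)), "")[[1]]
  k <- length(m)
  hits <- list()
  for (tx in names(transcripts)) {
    chars <- strsplit(toupper(gsub("U", "T", transcripts[[tx]],
                                   ignore.case = TRUE)), "")[[1]]
    M <- length(chars)
    if (M < k) next
    W <- M - k + 1L
    total <- numeric(W)
    # miRNA position i pairs with site position (k - i + 1); for window
    # starting at s, that's transcript position s + k - i.
    for (i in seq_len(k)) {
      pen_i <- .pair_penalty(m[i], chars, mismatch, wobble)
      total <- total + pen_i[(k - i + 1L):(k - i + W)]
    }
    sel <- which(total <= max_penalty)
    for (s in sel) {
      site <- paste(chars[s:(s + k - 1L)], collapse = "")
      pair_chars <- vapply(seq_len(k), function(i) {
        p <- .pair_penalty(m[i], chars[s + k - i], mismatch, wobble)
        if (p == 0) "|" else if (p == wobble && p != mismatch) "o" else "."
      }, character(1))
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = mirna_id, transcript_id = tx,
        site_start = s, site_end = s + k - 1L,
        penalty = total[s], site = site,
        pairing = paste(pair_chars, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    mirna_id = character(0), transcript_id = character(0),
    site_start = integer(0), site_end = integer(0), penalty = numeric(0),
    site = character(0), pairing = character(0), stringsAsFactors = FALSE
  )
  out[order(out$penalty, out$transcript_id, out$site_start), , drop = FALSE]
}
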