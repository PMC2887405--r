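# Input/output for per-locus alignments, sample panels and locus annotations,
# plus derivation of the gap-free core alignment every statistic operates on.
#
# Coordinate conventions: annotation files are BED-like (0-based, half-open);
# internally all coordinates are R-style 1-based closed intervals; report
# writers print 1-based inclusive coordinates.

VALID_BASES <- c("A", "C", "G", "T")
VALID_POPULATIONS <- c("cultivated", "wild", "outgroup")
VALID_SUBGROUPS <- c("indica", "japonica", "none")
VALID_CLASSES <- c("MIRNA", "TAS3", "long_hairpin", "neutral_reference")
VALID_CONSERVATION <- c("conserved", "species_specific", "not_applicable")
VALID_REGION_LABELS <- c(
  "mature", "precursor", "upstream", "downstream", "phase", "mir_binding_site"
)

#' Construct an aligned locus from sequences
#'
#' An `aligned_locus` holds one small-RNA locus' multiple sequence alignment
#' as a character matrix (rows = accessions, columns = alignment positions)
#' over the alphabet `A, C, G, T, -, N`.
#'
#' @param locus_id Locus identifier.
#' @param sequences Named character vector of aligned sequences (names are
#'   accession ids), all of identical length.
#' @return An object of class `aligned_locus`.
#' @export
aligned_locus <- function(locus_id, sequences) {
  if (length(sequences) < 1 || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("sequences must be a non-empty named character vector")
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate accession ids in locus '", locus_id, "'")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("unequal alignment lengths in locus '", locus_id, "'")
  }
  if (widths[1] == 0L) {
    stop("alignment of locus '", locus_id, "' has zero columns")
  }
  seqs <- toupper(sequences)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(sequences)
  bad <- setdiff(unique(as.vector(mat)), c(VALID_BASES, "-", "N"))
  if (length(bad)) {
    stop("invalid characters in alignment '", locus_id, "': ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(locus_id = locus_id, seq = mat),
    class = "aligned_locus"
  )
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(sprintf(
    "<aligned_locus> %s: %d sequences x %d columns\n",
    x$locus_id, nrow(x$seq), ncol(x$seq)
  ))
  invisible(x)
}

#' Alignment dimensions and accession ids
#'
#' @param locus An `aligned_locus` or `core_alignment`.
#' @return `alignment_length()` the number of columns; `accessions()` the
#'   accession ids in row order.
#' @export
alignment_length <- function(locus) ncol(locus$seq)

#' @rdname alignment_length
#' @export
accessions <- function(locus) rownames(locus$seq)

#' Read one locus alignment from an aligned FASTA file
#'
#' All records must have equal length (an alignment, not raw reads); bases
#' are uppercased. The locus id defaults to the file name stem.
#'
#' @param path Path to an aligned FASTA file with at least 2 records.
#' @param locus_id Optional override for the locus id.
#' @return An `aligned_locus`.
#' @export
read_alignment_fasta <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path)
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  if (length(set) < 2) stop("alignment needs >= 2 records: ", path)
  if (length(unique(Biostrings::width(set))) != 1L) {
    stop("unequal alignment lengths in ", path)
  }
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (is.null(locus_id)) {
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  }
  aligned_locus(locus_id, seqs)
}

#' Write an aligned locus to FASTA
#'
#' @param locus An `aligned_locus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(locus, path) {
  seqs <- apply(locus$seq, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read the sample panel table
#'
#' Tab-separated with header columns `accession_id`, `population`
#' (`cultivated`/`wild`/`outgroup`) and `subgroup` (`indica`/`japonica`/
#' `none`). Outgroup and wild entries must have subgroup `none`; cultivated
#' entries must carry a subgroup.
#'
#' @param path Path to the panel TSV.
#' @return A `population_panel` data frame.
#' @export
read_panel_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  population_panel(df)
}

#' @rdname read_panel_table
#' @param df Data frame with the three panel columns.
#' @export
population_panel <- function(df) {
  need <- c("accession_id", "population", "subgroup")
  if (!all(need %in% names(df))) {
    stop("panel table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$accession_id)) {
    stop("duplicate accession_id in panel: ",
         paste(unique(df$accession_id[duplicated(df$accession_id)]),
               collapse = ", "))
  }
  if (!all(df$population %in% VALID_POPULATIONS)) {
    stop("unknown population token(s): ",
         paste(setdiff(df$population, VALID_POPULATIONS), collapse = ", "))
  }
  if (!all(df$subgroup %in% VALID_SUBGROUPS)) {
    stop("unknown subgroup token(s): ",
         paste(setdiff(df$subgroup, VALID_SUBGROUPS), collapse = ", "))
  }
  bad <- df$population %in% c("outgroup", "wild") & df$subgroup != "none"
  if (any(bad)) {
    stop("outgroup/wild entries must have subgroup 'none': ",
         paste(df$accession_id[bad], collapse = ", "))
  }
  bad <- df$population == "cultivated" & df$subgroup == "none"
  if (any(bad)) {
    stop("cultivated entries must have subgroup indica or japonica: ",
         paste(df$accession_id[bad], collapse = ", "))
  }
  class(df) <- c("population_panel", "data.frame")
  df
}

#' Select accession ids from a panel
#'
#' @param panel A `population_panel`.
#' @param population Optional population filter.
#' @param subgroup Optional subgroup filter.
#' @return Character vector of accession ids.
#' @export
panel_accessions <- function(panel, population = NULL, subgroup = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(population)) keep <- keep & panel$population %in% population
  if (!is.null(subgroup)) keep <- keep & panel$subgroup %in% subgroup
  panel$accession_id[keep]
}

# Every accession in the locus must be resolvable in the panel.
check_panel_covers <- function(locus, panel) {
  missing <- setdiff(accessions(locus), panel$accession_id)
  if (length(missing)) {
    stop("accessions in locus '", locus$locus_id,
         "' absent from panel: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read locus region annotations
#'
#' BED-like TSV with header columns `locus_id`, `class`, `conservation`,
#' `label`, `name`, `start`, `end`; file coordinates are 0-based half-open
#' and are converted to 1-based closed intervals on read. Coordinates are
#' validated against alignment lengths only when joined to loci
#' (`validate_annotations()`), since the alignments are not yet known here.
#'
#' @param path Path to the annotation TSV.
#' @return A `locus_annotation` data frame (internal 1-based `start`/`end`).
#' @export
read_locus_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("locus_id", "class", "conservation", "label", "name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  locus_annotation(df, zero_based = TRUE)
}

#' @rdname read_locus_annotations
#' @param df Data frame of annotation rows.
#' @param zero_based If `TRUE`, `start`/`end` are 0-based half-open and are
#'   shifted to 1-based closed.
#' @export
locus_annotation <- function(df, zero_based = FALSE) {
  if (!all(df$class %in% VALID_CLASSES)) {
    stop("unknown locus class: ",
         paste(setdiff(df$class, VALID_CLASSES), collapse = ", "))
  }
  if (!all(df$conservation %in% VALID_CONSERVATION)) {
    stop("unknown conservation value: ",
         paste(setdiff(df$conservation, VALID_CONSERVATION), collapse = ", "))
  }
  if (!all(df$label %in% VALID_REGION_LABELS)) {
    stop("unknown region label: ",
         paste(setdiff(df$label, VALID_REGION_LABELS), collapse = ", "))
  }
  if (any(df$start >= df$end)) {
    stop("annotation rows with start >= end")
  }
  if (zero_based) {
    df$start <- df$start + 1L
  }
  if (any(df$start < 1L)) stop("annotation start below origin")
  df$name <- ifelse(is.na(df$name) | df$name == "", df$label, df$name)
  class(df) <- c("locus_annotation", "data.frame")
  df
}

#' Validate annotations against their loci
#'
#' Deferred checks: region coordinates must fit inside the matching
#' alignment and mature regions must nest inside the precursor when both
#' are annotated.
#'
#' @param annotations A `locus_annotation`.
#' @param loci A list of `aligned_locus` objects (names ignored; matched by
#'   `locus_id`).
#' @return Invisibly `TRUE`; errors describe the offending locus.
#' @export
validate_annotations <- function(annotations, loci) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  for (i in seq_len(nrow(annotations))) {
    row <- annotations[i, ]
    j <- match(row$locus_id, ids)
    if (is.na(j)) next # annotations for absent loci are not an error here
    len <- alignment_length(loci[[j]])
    if (row$end > len) {
      stop("annotation '", row$label, "' of locus '", row$locus_id,
           "' ends at ", row$end, " beyond alignment length ", len)
    }
  }
  # mature within precursor where both present
  for (id in unique(annotations$locus_id)) {
    sub <- annotations[annotations$locus_id == id, ]
    pre <- sub[sub$label == "precursor", ]
    mat <- sub[sub$label == "mature", ]
    if (nrow(pre) && nrow(mat)) {
      ok <- vapply(seq_len(nrow(mat)), function(k) {
        any(mat$start[k] >= pre$start & mat$end[k] <= pre$end)
      }, logical(1))
      if (!all(ok)) {
        stop("mature region not nested within precursor for locus '", id, "'")
      }
    }
  }
  invisible(TRUE)
}

#' Extract the gap-free core alignment
#'
#' Restricts an alignment to a subset of accessions and keeps exactly the
#' columns where every retained sequence has an unambiguous base
#' (`A/C/G/T`); any column containing `-` or `N` in any retained sequence
#' is dropped. The original column indices are recorded so that annotation
#' coordinates can be remapped into core coordinates.
#'
#' @param locus An `aligned_locus`.
#' @param subset Character vector of accession ids to retain (default: all).
#' @return A `core_alignment` with fields `locus_id`, `seq` (character
#'   matrix), `kept_columns` (original 1-based column indices) and `L`.
#' @export
extract_core_alignment <- function(locus, subset = NULL) {
  if (is.null(subset)) subset <- accessions(locus)
  if (length(subset) == 0) stop("empty accession subset")
  missing <- setdiff(subset, accessions(locus))
  if (length(missing)) {
    stop("accessions not in locus '", locus$locus_id, "': ",
         paste(missing, collapse = ", "))
  }
  mat <- locus$seq[subset, , drop = FALSE]
  ok <- colSums(matrix(mat %in% VALID_BASES, nrow = nrow(mat))) == nrow(mat)
  kept <- which(ok)
  if (length(kept) == 0) {
    warning("empty core alignment for locus '", locus$locus_id,
            "' (L = 0); downstream statistics are undefined")
  }
  structure(
    list(
      locus_id = locus$locus_id,
      seq = mat[, kept, drop = FALSE],
      kept_columns = kept,
      L = length(kept)
    ),
    class = "core_alignment"
  )
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf(
    "<core_alignment> %s: %d sequences x %d core columns\n",
    x$locus_id, nrow(x$seq), x$L
  ))
  invisible(x)
}

#' Map an alignment-coordinate region into core columns
#'
#' @param core A `core_alignment`.
#' @param start,end 1-based closed interval in original alignment
#'   coordinates.
#' @return Integer vector of core column indices (possibly empty when the
#'   region was entirely lost to gapped columns).
#' @export
map_region_to_core <- function(core, start, end) {
  which(core$kept_columns >= start & core$kept_columns <= end)
}
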