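# Orchestration of the two-step study design: (1) a diversity/neutrality
# survey of the cultivated panel; (2) the domestication-selection screen
# against wild and outgroup samples with HKA reference loci.
#
# Every stochastic step derives its child seed deterministically from the
# config seed, so reruns with the same config are bit-identical. Fixed-S
# Tajima null tables are drawn from one shared seeded stream (the null
# depends only on (n, S)), so they are reused across loci. Warnings (empty
# cores, NA statuses) never abort a run; missing inputs fail fast with the
# locus named.

#' Pipeline configuration
#'
#' @param input_dir Directory with per-locus FASTA alignments plus
#'   `panel.tsv` and `annotations.tsv` (alternative to `dataset`).
#' @param dataset An in-memory dataset (list with `loci`, `panel`,
#'   `annotations`), e.g. from [simulate_domestication_panel()].
#' @param output_dir Optional directory for TSV reports.
#' @param tajima_reps Fixed-S null replicates per Tajima test.
#' @param hka_sims Parametric simulations per HKA test.
#' @param alpha Significance level used everywhere (no multiple-testing
#'   correction is applied; noted in output headers).
#' @param reference_loci Locus ids to use as HKA/neutral-baseline
#'   references (default: all loci annotated `neutral_reference`).
#' @param seed Mandatory integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, dataset = NULL,
                            output_dir = NULL, tajima_reps = 10000,
                            hka_sims = 10000, alpha = 0.05,
                            reference_loci = NULL, seed) {
  if (missing(seed)) stop("pipeline_config requires an explicit seed")
  if (is.null(input_dir) && is.null(dataset)) {
    stop("provide input_dir or dataset")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  structure(
    list(
      input_dir = input_dir, dataset = dataset, output_dir = output_dir,
      tajima_reps = tajima_reps, hka_sims = hka_sims, alpha = alpha,
      reference_loci = reference_loci, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

.pipeline_data <- function(config) {
  if (!is.null(config$dataset)) config$dataset else read_dataset(config$input_dir)
}

.reference_ids <- function(config, data) {
  if (!is.null(config$reference_loci)) {
    missing <- setdiff(config$reference_loci, names(data$loci))
    if (length(missing)) {
      stop("reference loci absent from inputs: ",
           paste(missing, collapse = ", "))
    }
    return(config$reference_loci)
  }
  unique(data$annotations$locus_id[data$annotations$class == "neutral_reference"])
}

# per-locus conservation class (first annotated value)
.conservation_of <- function(annotations, id) {
  v <- annotations$conservation[annotations$locus_id == id]
  if (length(v)) v[1] else "not_applicable"
}

#' Step 1: diversity and neutrality survey of the cultivated panel
#'
#' For every locus: per-group (cultivated, indica, japonica) core
#' alignments, diversity statistics, region-partitioned diversity with
#' aggregates by region / conservation class / subgroup, Tajima's D with
#' fixed-S significance, the D histogram across loci, and the
#' functional-region mutation catalogue.
#'
#' @param config A [pipeline_config()].
#' @return List with `diversity`, `region_aggregates`, `tajima`,
#'   `d_histogram`, `mutations` (and TSVs under `output_dir` when set).
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- .pipeline_data(config)
  if (length(data$loci) == 0) stop("no loci to survey")
  validate_annotations(data$annotations, data$loci)
  groups <- list(
    cultivated = panel_accessions(data$panel, population = "cultivated"),
    indica = panel_accessions(data$panel, subgroup = "indica"),
    japonica = panel_accessions(data$panel, subgroup = "japonica")
  )
  null_seed <- derive_seed(config$seed, "tajima-null")
  div_rows <- list()
  taj_rows <- list()
  reg_rows <- list()
  cat_rows <- list()
  for (locus in data$loci) {
    id <- locus$locus_id
    check_panel_covers(locus, data$panel)
    for (g in names(groups)) {
      members <- intersect(groups[[g]], accessions(locus))
      if (length(members) < 2) next
      core <- extract_core_alignment(locus, members)
      if (core$L == 0) {
        warning("empty core for locus '", id, "' group '", g, "'; skipped")
        next
      }
      ds <- diversity_stats(core)
      ds$group <- g
      div_rows[[paste(id, g)]] <- ds
      if (nrow(core$seq) >= 3) {
        tt <- tajima_test(core, n_reps = config$tajima_reps,
                          seed = null_seed, alpha = config$alpha)
        tt$group <- g
        taj_rows[[paste(id, g)]] <- tt
      }
      rd <- region_diversity(locus, data$annotations, members)
      rd$group <- g
      rd$conservation <- .conservation_of(data$annotations, id)
      reg_rows[[paste(id, g)]] <- rd
    }
    cultivated <- intersect(groups$cultivated, accessions(locus))
    if (length(cultivated) >= 2) {
      mc <- catalog_region_mutations(locus, data$annotations, data$panel,
                                     cultivated)
      if (nrow(mc)) cat_rows[[id]] <- as.data.frame(mc)
    }
  }
  diversity <- do.call(rbind, div_rows)
  tajima <- do.call(rbind, taj_rows)
  regions <- do.call(rbind, reg_rows)
  rownames(diversity) <- rownames(tajima) <- rownames(regions) <- NULL
  aggregates <- list(
    by_region = aggregate_diversity(
      regions[regions$group == "cultivated", ], "region", "pi_site"
    ),
    by_region_snp = aggregate_diversity(
      regions[regions$group == "cultivated", ], "region", "snp_per_kb"
    ),
    by_conservation = aggregate_diversity(
      regions[regions$group == "cultivated", ],
      c("conservation", "region"), "pi_site"
    ),
    by_subgroup = aggregate_diversity(
      regions[regions$group %in% c("indica", "japonica"), ],
      c("group", "region"), "pi_site"
    )
  )
  d_hist <- if (!is.null(tajima) &&
                any(is.finite(tajima$D[tajima$group == "cultivated"]))) {
    d_distribution(tajima$D[tajima$group == "cultivated"])
  } else {
    NULL
  }
  mutations <- if (length(cat_rows)) do.call(rbind, cat_rows) else NULL
  out <- list(
    diversity = diversity, region_diversity = regions,
    region_aggregates = aggregates, tajima = tajima,
    d_histogram = d_hist, mutations = mutations
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        write_report_tsv(df, file.path(config$output_dir, name),
                         seed = config$seed, extra = "survey")
      }
    }
    wr(diversity, "diversity_per_locus.tsv")
    wr(aggregates$by_region, "diversity_by_region.tsv")
    wr(aggregates$by_conservation, "diversity_by_conservation.tsv")
    wr(aggregates$by_subgroup, "diversity_by_subgroup.tsv")
    wr(tajima, "tajima_per_locus.tsv")
    if (!is.null(d_hist)) wr(d_hist$histogram, "tajima_d_histogram.tsv")
    wr(mutations, "mutation_catalog.tsv")
  }
  out
}

#' Step 2: domestication-selection screen
#'
#' For each candidate locus and each population (indica, japonica, wild):
#' Tajima's D with fixed-S significance and the HKA test against the
#' neutral reference loci with the outgroup; plus the wild/cultivated
#' fold-reduction screen against the maximum reference-locus fold, and
#' the candidate classification.
#'
#' @param config A [pipeline_config()]; the panel must contain wild and
#'   outgroup samples and the inputs at least one reference locus.
#' @return List with `selection_table`, `fold_screen`, `baseline`,
#'   `tests` (long per-locus/group results).
#' @export
run_selection_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- .pipeline_data(config)
  validate_annotations(data$annotations, data$loci)
  ref_ids <- .reference_ids(config, data)
  if (length(ref_ids) == 0) stop("no reference loci available")
  cand_ids <- setdiff(names(data$loci), ref_ids)
  if (length(cand_ids) == 0) stop("no candidate loci to screen")
  wild <- panel_accessions(data$panel, population = "wild")
  outg <- panel_accessions(data$panel, population = "outgroup")
  if (length(wild) < 2) stop("selection screen requires a wild population")
  groups <- list(
    indica = panel_accessions(data$panel, subgroup = "indica"),
    japonica = panel_accessions(data$panel, subgroup = "japonica"),
    wild = wild
  )
  null_seed <- derive_seed(config$seed, "tajima-null")
  # HKA reference inputs per group
  ref_inputs <- list()
  for (g in names(groups)) {
    rows <- list()
    for (rid in ref_ids) {
      locus <- data$loci[[rid]]
      members <- intersect(groups[[g]], accessions(locus))
      og <- intersect(outg, accessions(locus))
      if (length(members) < 2 || length(og) < 1) next
      rows[[rid]] <- hka_inputs_from_alignment(locus, members, og,
                                               is_reference = TRUE)
    }
    ref_inputs[[g]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  tests <- list()
  pis <- list() # per (locus, group incl. wild) per-site pi for folds
  all_ids <- c(cand_ids, ref_ids)
  for (id in all_ids) {
    locus <- data$loci[[id]]
    for (g in names(groups)) {
      members <- intersect(groups[[g]], accessions(locus))
      if (length(members) < 2) {
        if (id %in% cand_ids) {
          warning("locus '", id, "': no usable ", g, " sample; tests NA")
        }
        next
      }
      core <- extract_core_alignment(locus, members)
      if (core$L == 0) next
      pp <- pairwise_pi(core)
      pis[[paste(id, g)]] <- data.frame(
        locus_id = id, group = g, pi_site = pp$pi_site,
        stringsAsFactors = FALSE
      )
      if (!(id %in% cand_ids)) next
      tt <- if (nrow(core$seq) >= 3) {
        tajima_test(core, n_reps = config$tajima_reps, seed = null_seed,
                    alpha = config$alpha)
      } else {
        data.frame(locus_id = id, n = nrow(core$seq), S = NA_integer_,
                   pi_locus = pp$pi_locus, D = NA_real_, p = NA_real_,
                   significant = FALSE, stringsAsFactors = FALSE)
      }
      hka_p <- NA_real_
      og <- intersect(outg, accessions(locus))
      if (length(og) >= 1 && !is.null(ref_inputs[[g]]) &&
          nrow(ref_inputs[[g]]) >= 1) {
        cand_in <- hka_inputs_from_alignment(locus, members, og)
        hka <- hka_candidate_test(
          cand_in, ref_inputs[[g]], n_sim = config$hka_sims,
          seed = derive_seed(config$seed, "hka", id, g),
          alpha = config$alpha
        )
        hka_p <- hka$p
      }
      tests[[paste(id, g)]] <- data.frame(
        locus_id = id, group = g, n = tt$n, S = tt$S, pi_locus = tt$pi_locus,
        pi_site = pp$pi_site, D = tt$D, d_p = tt$p,
        significant = tt$significant, hka_p = hka_p,
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  pis <- do.call(rbind, pis)
  rownames(pis) <- NULL
  # fold screen: baseline from reference loci (max over both subgroups)
  get_pi <- function(id, g) {
    v <- pis$pi_site[pis$locus_id == id & pis$group == g]
    if (length(v)) v[1] else NA_real_
  }
  ref_folds <- unlist(lapply(ref_ids, function(rid) {
    pw <- get_pi(rid, "wild")
    c(indica = if (!is.na(pw)) pw / get_pi(rid, "indica") else NA_real_,
      japonica = if (!is.na(pw)) pw / get_pi(rid, "japonica") else NA_real_)
  }))
  baseline <- neutral_baseline(ref_folds)
  fold_rows <- list()
  for (id in cand_ids) {
    pw <- get_pi(id, "wild")
    for (g in c("indica", "japonica")) {
      fr <- fold_reduction(pw, get_pi(id, g), baseline)
      fr <- cbind(data.frame(locus_id = id, subgroup = g,
                             stringsAsFactors = FALSE), fr)
      fold_rows[[paste(id, g)]] <- fr
    }
  }
  fold_screen <- do.call(rbind, fold_rows)
  rownames(fold_screen) <- NULL
  selection_table <- build_selection_table(tests, alpha = config$alpha)
  out <- list(
    selection_table = selection_table, fold_screen = fold_screen,
    baseline = baseline, tests = tests
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(selection_table,
                     file.path(config$output_dir, "selection_table.tsv"),
                     seed = config$seed, extra = "screen")
    write_report_tsv(fold_screen,
                     file.path(config$output_dir, "fold_screen.tsv"),
                     seed = config$seed, extra = "screen")
  }
  out
}
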