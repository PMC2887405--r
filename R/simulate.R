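# Coalescent synthetic-data generator and null-replicate engine.
#
# The generator emulates a rice resequencing study design: per-locus
# alignments of ~600 bp with cultivated (indica + japonica) samples drawn
# from a bottlenecked population that split from the wild population, plus
# a diverged outgroup. It also provides the neutral and fixed-S replicate
# streams used by the Tajima and HKA significance machinery.
#
# Model conventions: time in units of 2N generations; theta = 4Nu per locus
# unless suffixed _site; standard neutral coalescent (exponential waiting
# times at rate k(k-1)/2 scaled by relative population size); infinite-sites
# mutations mapped onto finite sequences by sampling distinct positions.

# --- branch accumulator -----------------------------------------------------
# Collects (length, ingroup-descendant count, outgroup-descendant count) per
# branch; environments avoid copy-on-write in the hot loops.

new_branch_acc <- function(n_total) {
  acc <- new.env(parent = emptyenv())
  m <- 2L * n_total # upper bound on branch count
  acc$blen <- numeric(m)
  acc$bcnt <- integer(m)
  acc$bout <- integer(m)
  acc$bi <- 0L
  acc
}

# Coalesce active lineages within [t, t_end] in a population of relative
# size `relsize`. `tm`/`cnt`/`out` describe the active lineages (node time,
# ingroup leaf count, outgroup leaf count). Returns the updated state.
coalesce_span <- function(tm, cnt, out, t, t_end, relsize, acc) {
  k <- length(tm)
  while (k >= 2L) {
    w <- stats::rexp(1L, k * (k - 1L) / 2) * relsize
    if (t + w > t_end) break
    t <- t + w
    ij <- sample.int(k, 2L)
    i <- min(ij)
    j <- max(ij)
    bi <- acc$bi
    acc$blen[bi + 1L] <- t - tm[i]
    acc$bcnt[bi + 1L] <- cnt[i]
    acc$bout[bi + 1L] <- out[i]
    acc$blen[bi + 2L] <- t - tm[j]
    acc$bcnt[bi + 2L] <- cnt[j]
    acc$bout[bi + 2L] <- out[j]
    acc$bi <- bi + 2L
    tm[i] <- t
    cnt[i] <- cnt[i] + cnt[j]
    out[i] <- out[i] + out[j]
    if (j < k) {
      tm[j] <- tm[k]
      cnt[j] <- cnt[k]
      out[j] <- out[k]
    }
    length(tm) <- length(cnt) <- length(out) <- k <- k - 1L
  }
  list(tm = tm, cnt = cnt, out = out, t = max(t, min(t_end, Inf)))
}

# Single-population genealogy of n samples coalesced to the root.
# Returns branch lengths and leaf counts (2n-2 branches).
sim_tree_onepop <- function(n) {
  acc <- new_branch_acc(n)
  coalesce_span(numeric(n), rep(1L, n), rep(0L, n), 0, Inf, 1, acc)
  k <- acc$bi
  list(blen = acc$blen[seq_len(k)], bcnt = acc$bcnt[seq_len(k)])
}

# Ingroup/outgroup genealogy for the HKA null: n ingroup lineages coalesce
# until the species split at time T, then join one outgroup lineage in an
# ancestral population of the same size. Returns per-branch lengths,
# ingroup counts and outgroup flags.
sim_tree_split <- function(n, T_split) {
  acc <- new_branch_acc(n + 1L)
  st <- coalesce_span(numeric(n), rep(1L, n), rep(0L, n), 0, T_split, 1, acc)
  tm <- c(st$tm, 0)
  cnt <- c(st$cnt, 0L)
  out <- c(st$out, 1L)
  coalesce_span(tm, cnt, out, T_split, Inf, 1, acc)
  k <- acc$bi
  list(
    blen = acc$blen[seq_len(k)],
    bcnt = acc$bcnt[seq_len(k)],
    bout = acc$bout[seq_len(k)]
  )
}

#' Simulate one neutral coalescent locus
#'
#' Standard neutral coalescent for `n` samples with per-locus mutation rate
#' `theta_locus` (= 4Nu); mutation counts are Poisson on total branch
#' length, each mutation assigned to a branch proportionally to its length.
#' Returns the summary statistics the pipeline estimates, enabling
#' calibration checks (E\[S\] = theta * a1(n), E\[pi\] = theta).
#'
#' @param n Number of sampled sequences (`n >= 2`).
#' @param theta_locus Per-locus population mutation rate (`>= 0`).
#' @param seed Optional integer seed (omit inside an outer seeded scope).
#' @return List with `S`, `pi_locus` and `total_length`.
#' @export
simulate_neutral_locus <- function(n, theta_locus, seed = NULL) {
  stopifnot(n >= 2, theta_locus >= 0)
  with_seed(seed, {
    tree <- sim_tree_onepop(n)
    tot <- sum(tree$blen)
    S <- stats::rpois(1L, theta_locus / 2 * tot)
    pi_locus <- 0
    if (S > 0L) {
      idx <- sample.int(length(tree$blen), S, replace = TRUE, prob = tree$blen)
      cc <- tree$bcnt[idx]
      pi_locus <- sum(cc * (n - cc)) / (n * (n - 1) / 2)
    }
    list(S = S, pi_locus = pi_locus, total_length = tot)
  })
}

#' Simulate a locus conditional on its number of segregating sites
#'
#' Fixed-S null replicate (Hudson's approach): a neutral genealogy is
#' simulated, then exactly `S` mutations are placed multinomially with
#' probabilities proportional to branch lengths. Used as the null for the
#' Tajima's D significance test.
#'
#' @param n Number of sequences.
#' @param S Number of segregating sites to place (`>= 1`).
#' @param seed Optional integer seed.
#' @return List with `pi_locus` and `S`.
#' @export
simulate_fixed_s <- function(n, S, seed = NULL) {
  stopifnot(n >= 2, S >= 1)
  with_seed(seed, {
    tree <- sim_tree_onepop(n)
    idx <- sample.int(length(tree$blen), S, replace = TRUE, prob = tree$blen)
    cc <- tree$bcnt[idx]
    list(pi_locus = sum(cc * (n - cc)) / (n * (n - 1) / 2), S = as.integer(S))
  })
}

# --- full genealogy with leaf sets (for sequence emission) ------------------

# Like coalesce_span but keeps the leaf-id set of every lineage so that
# mutations can be painted onto sequences. Only used at panel-emission
# volume. State: list(tm, leaves, t); acc env: blen, bleaves, bi.
coalesce_span_full <- function(state, t_end, relsize, acc) {
  tm <- state$tm
  leaves <- state$leaves
  t <- state$t
  k <- length(tm)
  while (k >= 2L) {
    w <- stats::rexp(1L, k * (k - 1L) / 2) * relsize
    if (t + w > t_end) break
    t <- t + w
    ij <- sample.int(k, 2L)
    i <- min(ij)
    j <- max(ij)
    bi <- acc$bi
    acc$blen[[bi + 1L]] <- t - tm[i]
    acc$bleaves[[bi + 1L]] <- leaves[[i]]
    acc$blen[[bi + 2L]] <- t - tm[j]
    acc$bleaves[[bi + 2L]] <- leaves[[j]]
    acc$bi <- bi + 2L
    tm[i] <- t
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])
    if (j < k) {
      tm[j] <- tm[k]
      leaves[[j]] <- leaves[[k]]
    }
    length(tm) <- k - 1L
    leaves[[k]] <- NULL
    k <- k - 1L
  }
  list(tm = tm, leaves = leaves, t = t_end)
}

new_full_acc <- function(n_total) {
  acc <- new.env(parent = emptyenv())
  acc$blen <- vector("list", 0L)
  acc$bleaves <- vector("list", 0L)
  acc$bi <- 0L
  acc
}

# Force a star-like post-sweep genealogy: all lineages merge (in random
# order) within a negligible time after `t0`.
star_collapse <- function(state, acc, eps = 1e-9) {
  tm <- state$tm
  leaves <- state$leaves
  t <- state$t
  k <- length(tm)
  while (k >= 2L) {
    t <- t + eps
    ij <- sample.int(k, 2L)
    i <- min(ij)
    j <- max(ij)
    bi <- acc$bi
    acc$blen[[bi + 1L]] <- t - tm[i]
    acc$bleaves[[bi + 1L]] <- leaves[[i]]
    acc$blen[[bi + 2L]] <- t - tm[j]
    acc$bleaves[[bi + 2L]] <- leaves[[j]]
    acc$bi <- bi + 2L
    tm[i] <- t
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])
    if (j < k) {
      tm[j] <- tm[k]
      leaves[[j]] <- leaves[[k]]
    }
    length(tm) <- k - 1L
    leaves[[k]] <- NULL
    k <- k - 1L
  }
  list(tm = tm, leaves = leaves, t = t)
}

# Single-population genealogy with leaf sets (for sequence emission).
sim_tree_onepop_full <- function(n) {
  acc <- new_full_acc(n)
  st <- list(tm = numeric(n), leaves = as.list(seq_len(n)), t = 0)
  coalesce_span_full(st, Inf, 1, acc)
  k <- acc$bi
  list(
    blen = unlist(acc$blen[seq_len(k)]),
    bleaves = acc$bleaves[seq_len(k)],
    n_total = n
  )
}

#' Simulate one neutral locus as an aligned FASTA-style alignment
#'
#' Sequence-level counterpart of [simulate_neutral_locus()]: a neutral
#' single-population coalescent whose infinite-sites mutations are painted
#' onto finite sequences of length `L`, so the full estimator chain
#' (core extraction, segregating sites, pi, theta, D) can be exercised.
#'
#' @param n Number of sequences.
#' @param L Sequence length (sites).
#' @param theta_site Per-site population mutation rate.
#' @param seed Optional integer seed.
#' @param locus_id Locus id of the returned alignment.
#' @return An `aligned_locus` with accessions `seq01..seqNN`.
#' @export
simulate_neutral_alignment <- function(n, L, theta_site, seed = NULL,
                                       locus_id = "simulated") {
  stopifnot(n >= 2, L > 0, theta_site >= 0)
  with_seed(seed, {
    tree <- sim_tree_onepop_full(n)
    mat <- emit_sequences(tree, L, theta_site, rep(1, L))
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("seq%02d", seq_len(n))
    aligned_locus(locus_id, seqs)
  })
}

# Structured genealogy for the domestication design. Sample order:
# cultivated (1..nc), wild, outgroup. Cultivated lineages pass (backward in
# time) through a bottleneck of relative size `strength` on
# [split - duration, split], then merge with the wild population at
# `split`; outgroup lineages join at `t_out`.
sim_tree_panel <- function(nc, nw, no, split, strength, duration, t_out,
                           sweep = FALSE, sweep_time = 0) {
  n_total <- nc + nw + no
  acc <- new_full_acc(n_total)
  bstart <- max(split - duration, 0)
  # cultivated
  cult <- list(tm = numeric(nc), leaves = as.list(seq_len(nc)), t = 0)
  if (sweep && nc >= 2) {
    # neutral accumulation since the sweep, then a star-like collapse at
    # the sweep completion time
    cult <- coalesce_span_full(cult, min(sweep_time, bstart), 1, acc)
    cult <- star_collapse(cult, acc)
    cult$t <- min(sweep_time, bstart)
  }
  cult <- coalesce_span_full(cult, bstart, 1, acc)
  cult <- coalesce_span_full(cult, split, strength, acc)
  # wild
  wild <- list(tm = numeric(nw), leaves = as.list(nc + seq_len(nw)), t = 0)
  wild <- coalesce_span_full(wild, split, 1, acc)
  # merged ingroup ancestral population until outgroup join
  anc <- list(
    tm = c(cult$tm, wild$tm),
    leaves = c(cult$leaves, wild$leaves),
    t = split
  )
  anc <- coalesce_span_full(anc, t_out, 1, acc)
  # outgroup population
  og <- list(
    tm = numeric(no),
    leaves = as.list(nc + nw + seq_len(no)),
    t = 0
  )
  if (no >= 2) og <- coalesce_span_full(og, t_out, 1, acc)
  # root population
  all <- list(
    tm = c(anc$tm, og$tm),
    leaves = c(anc$leaves, og$leaves),
    t = t_out
  )
  coalesce_span_full(all, Inf, 1, acc)
  k <- acc$bi
  list(
    blen = unlist(acc$blen[seq_len(k)]),
    bleaves = acc$bleaves[seq_len(k)],
    n_total = n_total
  )
}

# --- simulation configuration ----------------------------------------------

#' Default configuration for the synthetic domestication panel
#'
#' Defaults emulate the surveyed study design: ~600 bp loci; 17 indica + 16
#' japonica cultivated, 15 wild and 2 outgroup samples; a 21-nt mature
#' miRNA nested in a 120-nt precursor with flanking regions; per-region
#' mutation-rate multipliers enforcing stronger constraint on the mature
#' miRNA than on flanks; a domestication bottleneck reducing cultivated
#' diversity relative to wild; and a distant outgroup for divergence.
#'
#' @param n_loci Number of candidate small-RNA loci.
#' @param n_reference Number of neutral reference loci (no region
#'   structure; rate multiplier 1 everywhere).
#' @param locus_length Alignment length in bp.
#' @param theta_site Per-site population mutation rate of the wild
#'   population.
#' @param n_indica,n_japonica,n_wild,n_outgroup Samples per population.
#' @param split_time Wild/cultivated split, units of 2N generations.
#' @param bottleneck_strength Relative cultivated population size during
#'   the bottleneck, in (0, 1].
#' @param bottleneck_duration Bottleneck duration (2N units).
#' @param outgroup_divergence Outgroup join time T (2N units).
#' @param mature_multiplier,precursor_multiplier Mutation-rate multipliers
#'   for the mature miRNA and the rest of the precursor (flanks are 1).
#' @param indel_rate Expected number of short deletion events per locus
#'   (exercises core-alignment logic; 0 disables).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 10, n_reference = 4, locus_length = 600,
                       theta_site = 0.01,
                       n_indica = 17, n_japonica = 16, n_wild = 15,
                       n_outgroup = 2,
                       split_time = 0.1,
                       bottleneck_strength = 0.1, bottleneck_duration = 0.05,
                       outgroup_divergence = 5,
                       mature_multiplier = 0.3, precursor_multiplier = 0.6,
                       indel_rate = 0, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(
    n_loci >= 0, n_reference >= 0, locus_length > 0, theta_site >= 0,
    bottleneck_strength > 0, bottleneck_strength <= 1,
    bottleneck_duration >= 0, split_time >= 0,
    is.finite(outgroup_divergence), outgroup_divergence > split_time,
    mature_multiplier >= 0, precursor_multiplier >= 0, indel_rate >= 0
  )
  structure(
    list(
      n_loci = n_loci, n_reference = n_reference,
      locus_length = locus_length, theta_site = theta_site,
      n_indica = n_indica, n_japonica = n_japonica,
      n_wild = n_wild, n_outgroup = n_outgroup,
      split_time = split_time,
      bottleneck_strength = bottleneck_strength,
      bottleneck_duration = bottleneck_duration,
      outgroup_divergence = outgroup_divergence,
      mature_multiplier = mature_multiplier,
      precursor_multiplier = precursor_multiplier,
      indel_rate = indel_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Region layout of a simulated MIRNA locus (1-based closed, on the
# alignment): upstream flank, 120-nt precursor centred, 21-nt mature miRNA
# inside the precursor, downstream flank.
default_region_layout <- function(locus_length) {
  pre_len <- min(120L, locus_length)
  pre_start <- max(1L, (locus_length - pre_len) %/% 2L + 1L)
  pre_end <- pre_start + pre_len - 1L
  mat_len <- min(21L, pre_len)
  mat_start <- pre_start + (pre_len - mat_len) %/% 2L
  mat_end <- mat_start + mat_len - 1L
  layout <- data.frame(
    label = c("upstream", "precursor", "mature", "downstream"),
    start = c(1L, pre_start, mat_start, pre_end + 1L),
    end = c(pre_start - 1L, pre_end, mat_end, locus_length),
    stringsAsFactors = FALSE
  )
  layout[layout$start <= layout$end, , drop = FALSE]
}

# Per-site mutation-rate multipliers from a region layout.
region_site_weights <- function(layout, locus_length, mature_multiplier,
                                precursor_multiplier) {
  w <- rep(1, locus_length)
  pre <- layout[layout$label == "precursor", ]
  if (nrow(pre)) w[pre$start:pre$end] <- precursor_multiplier
  mat <- layout[layout$label == "mature", ]
  if (nrow(mat)) w[mat$start:mat$end] <- mature_multiplier
  w
}

# Paint mutations from a leafset genealogy onto finite sequences.
# Infinite-sites style: distinct positions sampled with probability
# proportional to the per-site weights; substitution base uniform among the
# three alternatives.
emit_sequences <- function(tree, locus_length, theta_site, weights) {
  n <- tree$n_total
  anc <- sample(VALID_BASES, locus_length, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  tot <- sum(tree$blen)
  # effective per-locus theta = theta_site * sum(weights)
  lambda <- theta_site * sum(weights) / 2 * tot
  n_mut <- stats::rpois(1L, lambda)
  if (n_mut > locus_length) {
    warning("mutation count exceeds locus length; truncating (saturation)")
    n_mut <- locus_length
  } else if (n_mut > 0.1 * locus_length) {
    warning("infinite-sites saturation above 10% of sites")
  }
  if (n_mut > 0L) {
    branches <- sample.int(length(tree$blen), n_mut, replace = TRUE,
                           prob = tree$blen)
    pos <- sample.int(locus_length, n_mut, replace = FALSE, prob = weights)
    for (m in seq_len(n_mut)) {
      leaves <- tree$bleaves[[branches[m]]]
      derived <- sample(setdiff(VALID_BASES, anc[pos[m]]), 1L)
      mat[leaves, pos[m]] <- derived
    }
  }
  mat
}

# Optional short deletion events (exercise gap handling): each event blanks
# a 1-6 bp run in one random sequence.
add_indels <- function(mat, indel_rate) {
  n_ev <- stats::rpois(1L, indel_rate)
  L <- ncol(mat)
  for (k in seq_len(n_ev)) {
    len <- sample.int(6L, 1L)
    start <- sample.int(max(L - len, 1L), 1L)
    row <- sample.int(nrow(mat), 1L)
    mat[row, start:(start + len - 1L)] <- "-"
  }
  mat
}

#' Simulate a complete domestication-study panel
#'
#' Generates `n_loci` candidate small-RNA loci plus `n_reference` neutral
#' reference loci under a three-population structured coalescent
#' (cultivated through a bottleneck, wild ancestral, diverged outgroup),
#' with per-region mutation-rate multipliers so that mature-miRNA diversity
#' is reduced relative to flanks. The emitted bundle (alignments, panel,
#' annotations) passes all `panel_io` validations and feeds every pipeline
#' stage.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `loci` (named list of
#'   `aligned_locus`), `panel` (`population_panel`), `annotations`
#'   (`locus_annotation`), `truth` (per-locus generating parameters) and
#'   `config`.
#' @export
simulate_domestication_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- config$n_indica + config$n_japonica
  ids <- c(
    sprintf("ind%02d", seq_len(config$n_indica)),
    sprintf("jap%02d", seq_len(config$n_japonica)),
    sprintf("wild%02d", seq_len(config$n_wild)),
    sprintf("outg%02d", seq_len(config$n_outgroup))
  )
  panel <- population_panel(data.frame(
    accession_id = ids,
    population = c(
      rep("cultivated", nc),
      rep("wild", config$n_wild),
      rep("outgroup", config$n_outgroup)
    ),
    subgroup = c(
      rep("indica", config$n_indica),
      rep("japonica", config$n_japonica),
      rep("none", config$n_wild + config$n_outgroup)
    ),
    stringsAsFactors = FALSE
  ))
  layout <- default_region_layout(config$locus_length)
  locus_ids <- c(
    if (config$n_loci > 0) sprintf("simMIR%03d", seq_len(config$n_loci)),
    if (config$n_reference > 0) sprintf("simREF%03d", seq_len(config$n_reference))
  )
  is_ref <- grepl("^simREF", locus_ids)
  loci <- vector("list", length(locus_ids))
  names(loci) <- locus_ids
  ann_rows <- list()
  truth <- list()
  for (li in seq_along(locus_ids)) {
    id <- locus_ids[li]
    loci[[li]] <- with_seed(derive_seed(config$seed, "locus", li), {
      weights <- if (is_ref[li]) {
        rep(1, config$locus_length)
      } else {
        region_site_weights(layout, config$locus_length,
                            config$mature_multiplier,
                            config$precursor_multiplier)
      }
      tree <- sim_tree_panel(
        nc, config$n_wild, config$n_outgroup,
        config$split_time, config$bottleneck_strength,
        config$bottleneck_duration, config$outgroup_divergence
      )
      mat <- emit_sequences(tree, config$locus_length, config$theta_site,
                            weights)
      if (config$indel_rate > 0) mat <- add_indels(mat, config$indel_rate)
      seqs <- apply(mat, 1, paste, collapse = "")
      names(seqs) <- ids
      aligned_locus(id, seqs)
    })
    if (is_ref[li]) {
      ann_rows[[id]] <- data.frame(
        locus_id = id, class = "neutral_reference",
        conservation = "not_applicable",
        label = "upstream", name = "whole",
        start = 1L, end = config$locus_length,
        stringsAsFactors = FALSE
      )
    } else {
      ann_rows[[id]] <- data.frame(
        locus_id = id, class = "MIRNA",
        conservation = if (li %% 2 == 0) "species_specific" else "conserved",
        label = layout$label, name = layout$label,
        start = layout$start, end = layout$end,
        stringsAsFactors = FALSE
      )
    }
    truth[[id]] <- data.frame(
      locus_id = id,
      is_reference = is_ref[li],
      swept = FALSE,
      theta_site = config$theta_site,
      split_time = config$split_time,
      bottleneck_strength = config$bottleneck_strength,
      bottleneck_duration = config$bottleneck_duration,
      outgroup_divergence = config$outgroup_divergence,
      stringsAsFactors = FALSE
    )
  }
  annotations <- locus_annotation(do.call(rbind, ann_rows))
  rownames(annotations) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(
    list(
      loci = loci, panel = panel, annotations = annotations,
      truth = truth, config = config
    ),
    class = "sim_dataset"
  )
}

#' Replace one locus with a cultivated-only selective sweep
#'
#' Re-simulates the named locus with a star-like (post-sweep) genealogy in
#' the cultivated population only: cultivated lineages coalesce essentially
#' instantaneously at the present, producing reduced diversity and an
#' excess of rare variants (negative Tajima's D) in cultivated samples
#' while wild and outgroup genealogies follow the neutral demography.
#'
#' @param dataset A `sim_dataset`.
#' @param locus_id Locus to replace.
#' @param sweep_time Sweep completion time in 2N units (default 0: a just
#'   completed sweep, the star genealogy proper, which zeroes cultivated
#'   polymorphism and maximizes the HKA diversity deficit). Positive
#'   values let cultivated lineages evolve neutrally for `sweep_time`
#'   before the collapse, leaving singleton-like rare variants and a
#'   negative Tajima's D at the cost of a weaker deficit.
#' @param seed Optional integer seed (defaults to a child of the config
#'   seed).
#' @return The modified `sim_dataset` (truth table marks the locus swept).
#' @export
inject_sweep_locus <- function(dataset, locus_id, sweep_time = NULL,
                               seed = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!locus_id %in% names(dataset$loci)) {
    stop("no such locus in dataset: ", locus_id)
  }
  config <- dataset$config
  nc <- config$n_indica + config$n_japonica
  if (is.null(sweep_time)) sweep_time <- 0
  if (is.null(seed)) seed <- derive_seed(config$seed, "sweep", locus_id)
  layout <- default_region_layout(config$locus_length)
  is_ref <- dataset$truth$is_reference[dataset$truth$locus_id == locus_id]
  dataset$loci[[locus_id]] <- with_seed(seed, {
    weights <- if (is_ref) {
      rep(1, config$locus_length)
    } else {
      region_site_weights(layout, config$locus_length,
                          config$mature_multiplier,
                          config$precursor_multiplier)
    }
    tree <- sim_tree_panel(
      nc, config$n_wild, config$n_outgroup,
      config$split_time, config$bottleneck_strength,
      config$bottleneck_duration, config$outgroup_divergence,
      sweep = TRUE, sweep_time = sweep_time
    )
    mat <- emit_sequences(tree, config$locus_length, config$theta_site,
                          weights)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- dataset$panel$accession_id
    aligned_locus(locus_id, seqs)
  })
  dataset$truth$swept[dataset$truth$locus_id == locus_id] <- TRUE
  dataset
}

#' Write a simulated dataset as the pipeline's input bundle
#'
#' Emits one aligned FASTA per locus, the panel TSV, the annotation TSV
#' (0-based half-open coordinates, as read back by
#' [read_locus_annotations()]) and a truth TSV of generating parameters.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in dataset$loci) {
    write_alignment_fasta(locus, file.path(dir, paste0(locus$locus_id, ".fasta")))
  }
  utils::write.table(
    as.data.frame(dataset$panel), file.path(dir, "panel.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ann <- as.data.frame(dataset$annotations)
  ann$start <- ann$start - 1L # print BED-like 0-based half-open
  utils::write.table(
    ann, file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    dataset$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Directory containing `*.fasta`, `panel.tsv` and
#'   `annotations.tsv`.
#' @return A list with `loci`, `panel`, `annotations`.
#' @export
read_dataset <- function(dir) {
  fastas <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(fastas) == 0) stop("no FASTA alignments found in ", dir)
  loci <- lapply(fastas, read_alignment_fasta)
  names(loci) <- vapply(loci, function(l) l$locus_id, character(1))
  panel <- read_panel_table(file.path(dir, "panel.tsv"))
  annotations <- read_locus_annotations(file.path(dir, "annotations.tsv"))
  for (locus in loci) check_panel_covers(locus, panel)
  validate_annotations(annotations, loci)
  list(loci = loci, panel = panel, annotations = annotations)
}
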