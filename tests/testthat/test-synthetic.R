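# Coalescent generator: analytic expectations, determinism, bottleneck
# behaviour, file round-trips and the sweep injection.

test_that("zero mutation rate yields identical sequences and S = 0", {
  out <- simulate_neutral_locus(6, 0, seed = 1)
  expect_equal(out$S, 0)
  expect_equal(out$pi_locus, 0)
  locus <- simulate_neutral_alignment(5, 80, 0, seed = 2)
  expect_equal(length(unique(apply(locus$seq, 1, paste, collapse = ""))), 1)
})

test_that("segregating sites match the coalescent expectation E[S] = theta a1", {
  reps <- 4000
  withr::with_seed(11, {
    s2 <- replicate(reps, simulate_neutral_locus(2, 3)$S)
  })
  se <- sd(s2) / sqrt(reps)
  expect_lt(abs(mean(s2) - 3), 3 * se)
  withr::with_seed(12, {
    s10 <- replicate(reps, simulate_neutral_locus(10, 5)$S)
  })
  a1 <- sum(1 / (1:9))
  se10 <- sd(s10) / sqrt(reps)
  expect_lt(abs(mean(s10) - 5 * a1), 3 * se10)
})

test_that("Watterson recovery on simulated neutral loci has small bias", {
  n <- 20
  L <- 600
  theta_site <- 0.005
  a1 <- sum(1 / seq_len(n - 1))
  withr::with_seed(13, {
    est <- replicate(500, {
      simulate_neutral_locus(n, theta_site * L)$S / a1 / L
    })
  })
  expect_lt(abs(mean(est) / theta_site - 1), 0.05)
})

test_that("the generator is deterministic given the config seed", {
  cfg <- sim_config(n_loci = 2, n_reference = 1, locus_length = 120,
                    n_indica = 4, n_japonica = 4, n_wild = 3,
                    n_outgroup = 1, seed = 99)
  d1 <- suppressWarnings(simulate_domestication_panel(cfg))
  d2 <- suppressWarnings(simulate_domestication_panel(cfg))
  expect_identical(
    lapply(d1$loci, function(l) l$seq),
    lapply(d2$loci, function(l) l$seq)
  )
  expect_identical(d1$truth, d2$truth)
  # fixed-S stream likewise
  expect_identical(simulate_fixed_s(10, 4, seed = 5),
                   simulate_fixed_s(10, 4, seed = 5))
})

test_that("emitted bundles re-read cleanly through panel_io", {
  cfg <- sim_config(n_loci = 2, n_reference = 1, locus_length = 150,
                    n_indica = 4, n_japonica = 3, n_wild = 3,
                    n_outgroup = 2, indel_rate = 1, seed = 17)
  ds <- suppressWarnings(simulate_domestication_panel(cfg))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_no_warning(back <- read_dataset(dir))
  expect_setequal(names(back$loci), names(ds$loci))
  for (id in names(ds$loci)) {
    expect_identical(back$loci[[id]]$seq, ds$loci[[id]]$seq)
  }
  expect_equal(as.data.frame(back$panel), as.data.frame(ds$panel))
  expect_equal(back$annotations$start, ds$annotations$start)
  expect_equal(back$annotations$end, ds$annotations$end)
})

test_that("a bottleneck reduces cultivated diversity monotonically", {
  pi_ratio <- function(strength, seed) {
    cfg <- sim_config(n_loci = 0, n_reference = 25, locus_length = 400,
                      n_indica = 6, n_japonica = 6, n_wild = 8,
                      n_outgroup = 1, bottleneck_strength = strength,
                      bottleneck_duration = 0.05, seed = seed)
    ds <- suppressWarnings(simulate_domestication_panel(cfg))
    cult <- panel_accessions(ds$panel, population = "cultivated")
    wild <- panel_accessions(ds$panel, population = "wild")
    folds <- vapply(ds$loci, function(locus) {
      pw <- pairwise_pi(extract_core_alignment(locus, wild))$pi_site
      pc <- pairwise_pi(extract_core_alignment(locus, cult))$pi_site
      c(pw, pc)
    }, numeric(2))
    mean(folds[1, ]) / mean(folds[2, ])
  }
  r_none <- pi_ratio(1, 301)
  r_mild <- pi_ratio(0.3, 302)
  r_severe <- pi_ratio(0.05, 303)
  # no bottleneck: cultivated and wild diversity agree within MC error
  expect_lt(abs(r_none - 1), 0.35)
  expect_gt(r_severe, r_mild)
  expect_gt(r_mild, r_none)
  expect_gt(r_severe, 1.5)
})

test_that("sweep injection empties cultivated diversity but spares wild", {
  cfg <- sim_config(n_loci = 2, n_reference = 0, locus_length = 300,
                    n_indica = 8, n_japonica = 8, n_wild = 8,
                    n_outgroup = 1, bottleneck_strength = 1,
                    bottleneck_duration = 0, seed = 401)
  ds <- suppressWarnings(simulate_domestication_panel(cfg))
  ds <- suppressWarnings(inject_sweep_locus(ds, "simMIR001"))
  expect_true(ds$truth$swept[ds$truth$locus_id == "simMIR001"])
  cult <- panel_accessions(ds$panel, population = "cultivated")
  wild <- panel_accessions(ds$panel, population = "wild")
  swept <- ds$loci[["simMIR001"]]
  expect_equal(
    find_segregating_sites(extract_core_alignment(swept, cult))$S, 0
  )
  # wild samples at the swept locus keep their variation (neutral marginal)
  s_wild <- find_segregating_sites(extract_core_alignment(swept, wild))$S
  expect_gt(s_wild, 0)
  expect_error(inject_sweep_locus(ds, "nope"), "no such locus")
})

test_that("stratified rates depress mature-region diversity below flanks", {
  cfg <- sim_config(n_loci = 40, n_reference = 0, locus_length = 300,
                    n_indica = 5, n_japonica = 5, n_wild = 2,
                    n_outgroup = 1, bottleneck_strength = 1,
                    bottleneck_duration = 0, mature_multiplier = 0.3,
                    precursor_multiplier = 0.6, seed = 55)
  ds <- suppressWarnings(simulate_domestication_panel(cfg))
  cult <- panel_accessions(ds$panel, population = "cultivated")
  mature <- numeric(0)
  flank <- numeric(0)
  for (locus in ds$loci) {
    rd <- region_diversity(locus, ds$annotations, cult)
    mature <- c(mature, rd$pi_site[rd$region == "mature"])
    flank <- c(flank, rd$pi_site[rd$region %in% c("upstream", "downstream")])
  }
  expect_lt(mean(mature, na.rm = TRUE), mean(flank, na.rm = TRUE))
})
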