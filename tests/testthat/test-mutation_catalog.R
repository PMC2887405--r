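# Functional-region mutation catalogue and the miRNA target-site scanner.

make_panel <- function(ids_ind, ids_jap, ids_wild = character(0)) {
  population_panel(data.frame(
    accession_id = c(ids_ind, ids_jap, ids_wild),
    population = c(rep("cultivated", length(ids_ind) + length(ids_jap)),
                   rep("wild", length(ids_wild))),
    subgroup = c(rep("indica", length(ids_ind)),
                 rep("japonica", length(ids_jap)),
                 rep("none", length(ids_wild))),
    stringsAsFactors = FALSE
  ))
}

test_that("region mutations are catalogued once per region with counts", {
  # 6 sequences, SNP at column 5 (inside mature), indel run at 12-13
  base <- strrep("A", 20)
  seqs <- setNames(rep(base, 6),
                   c("i1", "i2", "i3", "j1", "j2", "w1"))
  substr(seqs["i1"], 5, 5) <- "G"
  substr(seqs["i2"], 5, 5) <- "G"
  substr(seqs["w1"], 12, 13) <- "--"
  locus <- aligned_locus("mirZ", seqs)
  ann <- locus_annotation(data.frame(
    locus_id = "mirZ", class = "MIRNA", conservation = "conserved",
    label = c("mature", "phase"), name = c("mature", "P5'_5"),
    start = c(3, 10), end = c(9, 16), stringsAsFactors = FALSE
  ))
  panel <- make_panel(c("i1", "i2", "i3"), c("j1", "j2"), "w1")
  cat_ <- catalog_region_mutations(locus, ann, panel)
  expect_equal(nrow(cat_), 2)
  snp <- cat_[cat_$mutation_type == "SNP", ]
  expect_equal(snp$region, "mature")
  expect_equal(snp$position_in_region, 3) # 5' end of the region is base 1
  ind <- cat_[cat_$mutation_type == "indel", ]
  expect_equal(ind$region, "phase")
  expect_equal(ind$length, 2)
  # per-population percentages: G in 2 of 3 indica
  freq <- allele_frequencies_by_population(cat_, 1)
  gi <- freq[freq$group == "indica" & freq$allele == "G", ]
  expect_equal(gi$count, 2)
  expect_equal(gi$percent, 100 * 2 / 3, tolerance = 1e-10)
  for (g in unique(freq$group)) {
    expect_equal(sum(freq$percent[freq$group == g]), 100, tolerance = 1e-10)
  }
})

test_that("catalogue completeness: every in-region SNP, nothing outside", {
  set.seed(31)
  for (case in 1:15) {
    n <- 8
    L <- 50
    mat <- random_alignment_matrix(n, L, n_states = sample(2:3, 1))
    seqs <- apply(mat, 1, paste, collapse = "")
    locus <- aligned_locus("r", seqs)
    ann <- locus_annotation(data.frame(
      locus_id = "r", class = "MIRNA", conservation = "conserved",
      label = "mature", name = "mature", start = 11, end = 30,
      stringsAsFactors = FALSE
    ))
    panel <- make_panel(rownames(mat)[1:4], rownames(mat)[5:8])
    cat_ <- catalog_region_mutations(locus, ann, panel)
    core <- extract_core_alignment(locus)
    sites <- find_segregating_sites(core)$sites$alignment_position
    expected <- sites[sites >= 11 & sites <= 30]
    got <- cat_$alignment_position[cat_$mutation_type == "SNP"]
    expect_identical(sort(got), sort(expected))
    expect_false(any(duplicated(got)))
  }
})

test_that("mutation percentages reproduce the reported miR166e split", {
  # 17 cultivated accessions with G, 15 with A at the fourth mature base
  seqs <- setNames(rep(strrep("C", 30), 32), sprintf("c%02d", 1:32))
  substr(seqs[1:17], 10, 10) <- "G"
  substr(seqs[18:32], 10, 10) <- "A"
  locus <- aligned_locus("mir166e", seqs)
  ann <- locus_annotation(data.frame(
    locus_id = "mir166e", class = "MIRNA", conservation = "conserved",
    label = "mature", name = "mature", start = 7, end = 27,
    stringsAsFactors = FALSE
  ))
  panel <- make_panel(names(seqs)[1:16], names(seqs)[17:32])
  cat_ <- catalog_region_mutations(locus, ann, panel)
  expect_equal(cat_$position_in_region, 4)
  freq <- allele_frequencies_by_population(cat_, 1)
  cult <- freq[freq$group %in% c("indica", "japonica"), ]
  g_total <- sum(cult$count[cult$allele == "G"])
  a_total <- sum(cult$count[cult$allele == "A"])
  expect_equal(g_total, 17)
  expect_equal(a_total, 15)
  expect_equal(100 * g_total / 32, 53.1, tolerance = 0.1)
  expect_equal(100 * a_total / 32, 46.9, tolerance = 0.1)
})

test_that("no variants means an empty catalogue", {
  seqs <- setNames(rep(strrep("G", 15), 4), c("i1", "i2", "j1", "j2"))
  locus <- aligned_locus("flat", seqs)
  ann <- locus_annotation(data.frame(
    locus_id = "flat", class = "MIRNA", conservation = "conserved",
    label = "mature", name = "mature", start = 2, end = 12,
    stringsAsFactors = FALSE
  ))
  cat_ <- catalog_region_mutations(locus, ann,
                                   make_panel(c("i1", "i2"), c("j1", "j2")))
  expect_equal(nrow(cat_), 0)
})

test_that("target penalties follow the pairing rules and add up", {
  mirna <- "UGGAAUGUAAAGAAGUAUGGAG" # 22 nt
  # perfect antiparallel complement: reverse complement with U -> T
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(gsub("U", "T", x), "")[[1]]]), collapse = "")
  }
  site <- rc(mirna)
  expect_equal(target_penalty_score(mirna, site), 0)
  # one G:U wobble: pair the 5'-terminal U of the miRNA with G
  site_wobble <- site
  substr(site_wobble, 22, 22) <- "G"
  expect_equal(target_penalty_score(mirna, site_wobble), 0.5)
  # two mismatches and one wobble accumulate
  site3 <- site_wobble
  substr(site3, 1, 1) <- "A" # mismatch against 3'-terminal G
  substr(site3, 2, 2) <- "G" # mismatch against A
  expect_equal(target_penalty_score(mirna, site3), 2.5)
  # U and T encodings are interchangeable
  expect_equal(
    target_penalty_score(gsub("U", "T", mirna), gsub("T", "U", site_wobble)),
    0.5
  )
  expect_error(target_penalty_score("ACGU", "ACGUA"), "equal lengths")
})

test_that("scanning finds exact sites and honors the penalty cap", {
  mirna <- "UGGAAUGUAAAGAAGUAUGGAG"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  site <- paste(rev(comp[strsplit(gsub("U", "T", mirna), "")[[1]]]),
                collapse = "")
  set.seed(61)
  tx <- paste0(random_seq(40), site, random_seq(40))
  hits <- scan_targets(mirna, c(myTx = tx), max_penalty = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_start, 41)
  expect_equal(hits$penalty, 0)
  expect_equal(hits$pairing, strrep("|", 22))
  # a wobbled site is excluded at cap 0 but found at cap 0.5
  site_wobble <- site
  substr(site_wobble, 22, 22) <- "G"
  tx2 <- paste0(random_seq(30), site_wobble, random_seq(30))
  expect_equal(nrow(scan_targets(mirna, c(t = tx2), max_penalty = 0)), 0)
  h2 <- scan_targets(mirna, c(t = tx2), max_penalty = 0.5)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$penalty, 0.5)
})

test_that("scanning equals brute-force window enumeration", {
  set.seed(71)
  for (case in 1:120) {
    k <- sample(18:24, 1)
    mirna <- random_seq(k)
    txs <- setNames(
      vapply(1:2, function(i) random_seq(sample(k:120, 1)), character(1)),
      c("t1", "t2")
    )
    cap <- sample(c(4, 6, 8), 1)
    got <- scan_targets(mirna, txs, max_penalty = cap)
    want <- brute_force_scan(mirna, txs, cap)
    got <- got[order(got$transcript_id, got$site_start), ]
    want <- want[order(want$transcript_id, want$site_start), ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$transcript_id, want$transcript_id)
      expect_equal(got$site_start, want$site_start)
      expect_equal(got$penalty, want$penalty)
    }
  }
})
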