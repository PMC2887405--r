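# Alignment, panel and annotation I/O plus core-alignment extraction.

test_that("aligned FASTA round-trips exactly and normalizes case", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mirX.fasta")
  writeLines(c(">acc1", "acgtACGTnn", ">acc2 extra words", "AC-TACGTNN",
               ">acc3", "ACGTACGTAA"), path)
  locus <- read_alignment_fasta(path)
  expect_equal(locus$locus_id, "mirX")
  expect_equal(alignment_length(locus), 10)
  expect_equal(accessions(locus), c("acc1", "acc2", "acc3"))
  expect_equal(paste(locus$seq["acc1", ], collapse = ""), "ACGTACGTNN")
  out <- file.path(dir, "roundtrip.fasta")
  write_alignment_fasta(locus, out)
  back <- read_alignment_fasta(out, locus_id = locus$locus_id)
  expect_identical(back$seq, locus$seq)
  expect_identical(back$locus_id, locus$locus_id)
})

test_that("malformed alignments are rejected with clear errors", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "bad.fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), p1)
  expect_error(read_alignment_fasta(p1), "unequal alignment lengths")
  p2 <- file.path(dir, "empty.fasta")
  writeLines(character(0), p2)
  expect_error(read_alignment_fasta(p2), "empty|readable")
  p3 <- file.path(dir, "single.fasta")
  writeLines(c(">a", "ACGT"), p3)
  expect_error(read_alignment_fasta(p3), ">= 2 records")
  expect_error(aligned_locus("x", c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(aligned_locus("x", c(a = "ACXT", b = "ACGT")), "invalid")
})

test_that("panel tables are validated on read", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.tsv")
  writeLines(c("accession_id\tpopulation\tsubgroup",
               "a1\tcultivated\tindica",
               "w1\twild\tnone",
               "o1\toutgroup\tnone"), p)
  panel <- read_panel_table(p)
  expect_s3_class(panel, "population_panel")
  expect_equal(nrow(panel), 3)
  expect_equal(panel_accessions(panel, population = "wild"), "w1")
  expect_equal(panel_accessions(panel, subgroup = "indica"), "a1")

  bad <- data.frame(accession_id = c("a", "a"),
                    population = "cultivated", subgroup = "indica")
  expect_error(population_panel(bad), "duplicate")
  bad2 <- data.frame(accession_id = "o1", population = "outgroup",
                     subgroup = "indica")
  expect_error(population_panel(bad2), "subgroup 'none'")
  bad3 <- data.frame(accession_id = "x", population = "landrace",
                     subgroup = "none")
  expect_error(population_panel(bad3), "unknown population")
  bad4 <- data.frame(accession_id = "c1", population = "cultivated",
                     subgroup = "none")
  expect_error(population_panel(bad4), "indica or japonica")
})

test_that("annotations convert BED-like coordinates and defer length checks", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ann.tsv")
  writeLines(c(
    "locus_id\tclass\tconservation\tlabel\tname\tstart\tend",
    "mir166e\tMIRNA\tconserved\tmature\tmature\t120\t141",
    "mir166e\tMIRNA\tconserved\tprecursor\tprecursor\t100\t220",
    "tas3a\tTAS3\tnot_applicable\tphase\tP5'_5\t10\t31",
    "tas3a\tTAS3\tnot_applicable\tphase\tP5'_9\t94\t115"
  ), p)
  ann <- read_locus_annotations(p)
  # 0-based half-open [120, 141) becomes 1-based closed [121, 141]
  expect_equal(ann$start[1], 121)
  expect_equal(ann$end[1], 141)
  expect_equal(ann$end[1] - ann$start[1] + 1, 21)
  expect_equal(sum(ann$locus_id == "tas3a" & ann$label == "phase"), 2)

  bad <- data.frame(locus_id = "x", class = "MIRNA",
                    conservation = "conserved", label = "mature",
                    name = "m", start = 50, end = 50)
  expect_error(locus_annotation(bad), "start >= end")
  bad2 <- data.frame(locus_id = "x", class = "MIRNA",
                     conservation = "conserved", label = "loop",
                     name = "m", start = 1, end = 10)
  expect_error(locus_annotation(bad2), "unknown region label")

  # deferred validation: region beyond the alignment fails when joined
  locus <- aligned_locus("mir166e", c(a = strrep("A", 150),
                                      b = strrep("C", 150)))
  expect_error(validate_annotations(ann, list(locus)), "beyond alignment")
  locus2 <- aligned_locus("mir166e", c(a = strrep("A", 300),
                                       b = strrep("C", 300)))
  tas <- aligned_locus("tas3a", c(a = strrep("A", 200), b = strrep("C", 200)))
  expect_true(validate_annotations(ann, list(locus2, tas)))
})

test_that("core alignment keeps exactly the gap- and N-free columns", {
  locus <- aligned_locus("x", c(a = "AC-T", b = "ACGT"))
  core <- extract_core_alignment(locus)
  expect_equal(core$kept_columns, c(1, 2, 4))
  expect_equal(core$L, 3)
  # gap-free input is the identity
  locus2 <- random_locus(4, 25)
  core2 <- extract_core_alignment(locus2)
  expect_equal(core2$L, 25)
  expect_identical(core2$seq, locus2$seq)
  # N counts as missing like a gap
  locus3 <- aligned_locus("x", c(a = "ANGT", b = "ACGT"))
  expect_equal(extract_core_alignment(locus3)$kept_columns, c(1, 3, 4))
  # empty core is flagged
  locus4 <- aligned_locus("x", c(a = "--", b = "AC"))
  expect_warning(core4 <- extract_core_alignment(locus4), "empty core")
  expect_equal(core4$L, 0)
  expect_error(extract_core_alignment(locus, character(0)), "empty")
  expect_error(extract_core_alignment(locus, c("a", "zzz")), "not in locus")
})

test_that("core extraction is idempotent and monotone in the subset", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    L <- sample(10:40, 1)
    mat <- random_alignment_matrix(n, L)
    # punch random gaps/Ns
    holes <- sample(length(mat), round(0.1 * length(mat)))
    mat[holes] <- sample(c("-", "N"), length(holes), replace = TRUE)
    seqs <- apply(mat, 1, paste, collapse = "")
    locus <- aligned_locus("r", seqs)
    subsets <- lapply(2:n, function(k) accessions(locus)[1:k])
    Ls <- vapply(subsets, function(s) {
      suppressWarnings(extract_core_alignment(locus, s)$L)
    }, numeric(1))
    # adding accessions never increases L
    expect_true(all(diff(Ls) <= 0))
    # idempotence: re-extracting the core's own columns changes nothing
    core <- suppressWarnings(extract_core_alignment(locus))
    again <- aligned_locus("r2", apply(core$seq, 1, paste, collapse = ""))
    core2 <- extract_core_alignment(again)
    expect_equal(core2$L, core$L)
    expect_equal(unname(core2$seq), unname(core$seq))
  }
})

test_that("region remapping preserves order and never collapses columns", {
  set.seed(7)
  locus <- random_locus(4, 60)
  mat <- locus$seq
  mat[2, c(5, 6, 20, 40:44)] <- "-"
  locus <- aligned_locus("g", apply(mat, 1, paste, collapse = ""))
  core <- extract_core_alignment(locus)
  idx <- map_region_to_core(core, 10, 50)
  expect_true(all(diff(idx) > 0))
  orig <- core$kept_columns[idx]
  expect_true(all(orig >= 10 & orig <= 50))
  expect_false(any(duplicated(orig)))
  # region entirely lost from the core maps to nothing
  expect_length(map_region_to_core(core, 40, 44), 0)
})
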