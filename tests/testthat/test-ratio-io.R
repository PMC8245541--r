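# small proteinGroups fixture written in code
make_pg_fixture <- function(path, rows) {
  header <- c("Protein IDs", "Gene names", "Reverse",
              "Potential contaminant", "Only identified by site",
              "Ratio H/M normalized rep1", "Ratio H/M normalized rep2")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

test_that("reader filters artifact rows and counts them", {
  rows <- c(
    lapply(1:8, function(i)
      c(sprintf("P%02d;P%02d-2", i, i), sprintf("G%d", i), "", "", "",
        "1.1", "0.9")),
    list(c("REV__X1", "", "+", "", "", "1.0", "1.0"),
         c("CON__K1", "KRT1", "", "+", "", "2.0", "2.0")))
  path <- withr::local_tempfile(fileext = ".txt")
  make_pg_fixture(path, rows)
  tab <- read_protein_groups(path)
  expect_identical(nrow(tab$ratios), 8L)
  expect_identical(attr(tab, "filter_report"),
                   c(reverse = 1L, contaminant = 1L, only_site = 0L))
  # leading accession is the key; gene kept as annotation
  expect_identical(rownames(tab$ratios)[1], "P01")
  expect_identical(tab$gene[1], "G1")
})

test_that("zero, empty and NaN ratio cells become missing, never 0.0", {
  rows <- list(c("P1", "", "", "", "", "0", "1.5"),
               c("P2", "", "", "", "", "", "NaN"),
               c("P3", "", "", "", "", "0.8", "1.2"))
  path <- withr::local_tempfile(fileext = ".txt")
  make_pg_fixture(path, rows)
  tab <- read_protein_groups(path)
  expect_identical(tab$ratios["P1", ], c(rep1 = NA_real_, rep2 = 1.5))
  expect_true(all(is.na(tab$ratios["P2", ])))
  expect_false(any(tab$ratios == 0, na.rm = TRUE))
})

test_that("missing ratio columns and duplicate ids are configuration errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Protein IDs\tGene names", "P1\tG1"), path)
  expect_error(read_protein_groups(path), "Ratio H/M normalized")

  rows <- list(c("P1;A", "", "", "", "", "1", "1"),
               c("P1;B", "", "", "", "", "1", "1"))
  path2 <- withr::local_tempfile(fileext = ".txt")
  make_pg_fixture(path2, rows)
  expect_error(read_protein_groups(path2), "duplicate")
})

test_that("only-identified-by-site filtering is on by default and configurable", {
  rows <- list(c("P1", "", "", "", "+", "1", "1"),
               c("P2", "", "", "", "", "1", "1"))
  path <- withr::local_tempfile(fileext = ".txt")
  make_pg_fixture(path, rows)
  expect_identical(nrow(read_protein_groups(path)$ratios), 1L)
  kept <- read_protein_groups(path, filter_only_site = FALSE)
  expect_identical(nrow(kept$ratios), 2L)
})

test_that("orientation keeps forward ratios and inverts swapped ones", {
  mat <- matrix(c(2.0, 0.5, 2.0, 0.5), 2, 2,
                dimnames = list(c("P1", "P2"), c("f", "s")))
  tab <- ratio_table(mat)
  des <- label_design(c("f", "s"), c("forward", "swapped"))
  ori <- orient_ratios(tab, des)
  expect_identical(ori$ratios["P1", "f"], 2.0)   # forward: identity
  expect_identical(ori$ratios["P1", "s"], 0.5)   # swapped: 1/2.0
  expect_identical(ori$ratios["P2", "s"], 2.0)   # swapped: 1/0.5
  expect_true(ori$oriented)

  # missing stays missing
  mat[1, 2] <- NA
  ori2 <- orient_ratios(ratio_table(mat), des)
  expect_true(is.na(ori2$ratios[1, 2]))
})

test_that("design coverage is enforced in both directions", {
  tab <- ratio_table(matrix(1, 1, 2, dimnames = list("P1", c("a", "b"))))
  expect_error(orient_ratios(tab, label_design("a", "forward")),
               "lacks replicates: b")
  expect_error(
    orient_ratios(tab, label_design(c("a", "b", "c"),
                                    rep("forward", 3))),
    "unknown replicate ids: c")
  expect_error(label_design(c("a", "a"), c("forward", "swapped")),
               "unique")
})

test_that("all-forward orientation is idempotent; all-swapped is an involution", {
  set.seed(21)
  tab <- random_ratio_table(30, 4)
  fwd <- label_design(colnames(tab$ratios), rep("forward", 4))
  sw <- label_design(colnames(tab$ratios), rep("swapped", 4))
  expect_identical(orient_ratios(tab, fwd)$ratios, tab$ratios)
  twice <- orient_ratios(orient_ratios(tab, sw), sw)
  expect_equal(twice$ratios, tab$ratios, tolerance = 1e-12)
  # one application is not the identity
  expect_false(isTRUE(all.equal(orient_ratios(tab, sw)$ratios,
                                tab$ratios)))
})

test_that("flipping every swap flag in generator and design leaves the pipeline invariant", {
  for (seed in 1:5) {
    pat <- rep_len(c("forward", "swapped"), 5)
    flip <- ifelse(pat == "forward", "swapped", "forward")
    cfg1 <- sim_config(n_proteins = 120, n_replicates = 5,
                       swap_pattern = pat, seed = seed)
    cfg2 <- sim_config(n_proteins = 120, n_replicates = 5,
                       swap_pattern = flip, seed = seed)
    s1 <- simulate_experiment(cfg1)
    s2 <- simulate_experiment(cfg2)
    o1 <- orient_ratios(s1$table, s1$design)
    o2 <- orient_ratios(s2$table, s2$design)
    expect_equal(o1$ratios, o2$ratios, tolerance = 1e-12)
    c1 <- run_screen(o1); c2 <- run_screen(o2)
    expect_identical(c1$class, c2$class)
    expect_identical(c1[c("n_detected", "n_up", "n_down")],
                     c2[c("n_detected", "n_up", "n_down")])
    expect_equal(c1$mean_ratio, c2$mean_ratio, tolerance = 1e-12)
  }
})

test_that("canonical oriented TSV round-trips", {
  set.seed(5)
  tab <- random_ratio_table(25, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_table(tab, path)
  back <- read_ratio_table(path)
  expect_equal(back$ratios, tab$ratios, tolerance = 1e-6)
  expect_true(back$oriented)
})

test_that("label designs load from TSV and YAML alike", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("replicate_id\torientation\tcohort",
               "rep1\tforward\tyoung", "rep2\tswapped\tyoung"), tsv)
  d1 <- read_label_design(tsv)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("replicates:",
               "- {replicate_id: rep1, orientation: forward, cohort: young}",
               "- {replicate_id: rep2, orientation: swapped, cohort: young}"),
             yml)
  d2 <- read_label_design(yml)
  expect_identical(d1$orientation, d2$orientation)
  expect_identical(d1$replicate_id, d2$replicate_id)
  expect_identical(d1$cohort, d2$cohort)
})
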