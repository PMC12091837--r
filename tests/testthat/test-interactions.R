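test_that("reading a VDJdb-style table maps columns and validates rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    `antigen.epitope` = c("GILGFVFTL", "NLVPMVATV", "GILGFVxTL"),
    cdr3 = c("CASSF", "CASSG", "CASSH"),
    `mhc.a` = c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02")), path)

  ds <- read_interaction_table(path)
  expect_equal(nrow(ds), 2L)
  expect_setequal(ds$peptide, c("GILGFVFTL", "NLVPMVATV"))
  expect_true(all(ds$label == 1L))
  expect_true(all(ds$source == "observed"))
  report <- attr(ds, "drop_report")
  expect_equal(report$n[report$reason == "invalid_alphabet"], 1L)
})

test_that("a table lacking the mapped cdr3b column is a schema error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(`antigen.epitope` = "GILGFVFTL",
                                  other = "x"), path)
  expect_error(read_interaction_table(path), class = "tcrsplit_schema_error")
})

test_that("an empty table is an empty-dataset error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("antigen.epitope\tcdr3", path)
  expect_error(read_interaction_table(path), class = "tcrsplit_empty_error")
})

test_that("duplicate (peptide, cdr3b, label) rows are collapsed", {
  ds <- as_interactions(tibble::tibble(
    peptide = c("AAAAA", "AAAAA", "AAAAA"),
    cdr3b = c("CASSF", "CASSF", "CASSF"),
    label = c(1L, 1L, 0L)))
  expect_equal(nrow(ds), 2L)
  expect_setequal(ds$label, c(0L, 1L))
})

test_that("filtering drops incomplete records and applies MHC globs", {
  ds <- tibble::tibble(
    peptide = c("AAAAA", "CCCCC", "DDDDD", "EEEEE", "FFFFF"),
    cdr3b = c("CASF", NA, "", "CASG", "CASH"),
    cdr3a = NA_character_,
    mhc_allele = c("HLA-A*02:01", "HLA-A*01:01", "HLA-A*03:01",
                   "HLA-DRB1*01:01", NA),
    label = 1L, source = "observed")

  expect_equal(nrow(filter_interactions(ds)), 3L)
  cls1 <- filter_interactions(ds, mhc_pattern = "HLA-A*")
  expect_equal(cls1$peptide, "AAAAA")
  expect_identical(filter_interactions(ds, require_cdr3b = FALSE,
                                       require_peptide = FALSE), ds)
})

test_that("peptide_counts reports exact multiplicities", {
  ds <- as_interactions(tibble::tibble(
    peptide = c("AAAAA", "AAAAA", "CCCCC"),
    cdr3b = c("CASF", "CASG", "CASH")))
  counts <- peptide_counts(ds)
  expect_equal(counts$n[counts$peptide == "AAAAA"], 2L)
  expect_equal(counts$n[counts$peptide == "CCCCC"], 1L)
})

test_that("negative generation draws exactly the non-positive combinations", {
  pos <- as_interactions(tibble::tibble(
    peptide = c("AAAAA", "CCCCC"),
    cdr3b = c("CASF", "CASG"),
    label = 1L))
  ## 2x2 grid minus 2 positives leaves exactly {(A,CASG),(C,CASF)}
  aug <- generate_negatives(pos, 2L, seed = 5)
  neg <- aug[aug$label == 0L, ]
  expect_setequal(paste(neg$peptide, neg$cdr3b),
                  c("AAAAA CASG", "CCCCC CASF"))
  expect_true(all(neg$source == "shuffled"))
  expect_error(generate_negatives(pos, 3L, seed = 1),
               class = "tcrsplit_infeasible_error")
})

test_that("negatives are label-disjoint from positives, closed, reproducible", {
  withr::with_seed(42, {
    pos <- as_interactions(tibble::tibble(
      peptide = rep(replicate(8, random_peptide(9)), each = 5),
      cdr3b = replicate(40, random_peptide(12)),
      label = 1L))
  })
  a <- generate_negatives(pos, 30L, seed = 7)
  b <- generate_negatives(pos, 30L, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_negatives(pos, 30L, seed = 8)))

  neg <- a[a$label == 0L, ]
  expect_equal(nrow(neg), 30L)
  expect_equal(anyDuplicated(paste(neg$peptide, neg$cdr3b)), 0L)
  ## no (peptide, cdr3b) appears with both labels
  expect_length(intersect(paste(neg$peptide, neg$cdr3b),
                          paste(pos$peptide, pos$cdr3b)), 0L)
  ## closure: shuffling, not invention
  expect_true(all(neg$peptide %in% pos$peptide))
  expect_true(all(neg$cdr3b %in% pos$cdr3b))
})

test_that("generate_negatives with n = 0 is the identity", {
  pos <- tiny_interactions() |> as_interactions()
  expect_identical(generate_negatives(pos, 0L, seed = 1), pos)
})

test_that("interaction tables round-trip through the canonical TSV format", {
  ds <- generate_negatives(as_interactions(tiny_interactions()), 2L,
                           seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_table(ds, path)
  back <- read_interaction_table(path)
  expect_equal(back$peptide, ds$peptide)
  expect_equal(back$cdr3b, ds$cdr3b)
  expect_equal(back$label, ds$label)
  expect_equal(back$source, ds$source)
})
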