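test_that("generated peptides are unique, in range, and reproducible", {
  spec <- fixture_spec(n_peptides = 100, seed = 9)
  peps <- generate_peptides(spec)
  expect_equal(nrow(peps), 100L)
  expect_equal(anyDuplicated(peps$peptide), 0L)
  expect_true(all(nchar(peps$peptide) >= 8 & nchar(peps$peptide) <= 11))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peps$peptide)))
  expect_identical(generate_peptides(spec), peps)

  uni <- fixture_spec(n_peptides = 20, count_distribution = "uniform",
                      uniform_count = 7L)
  expect_true(all(generate_peptides(uni)$count == 7L))
})

test_that("skewed counts are heavy-tailed: median below mean", {
  spec <- fixture_spec(n_peptides = 500, seed = 10)
  counts <- generate_peptides(spec)$count
  expect_lt(median(counts), mean(counts))
  expect_gte(min(counts), 1L)
})

test_that("fixture_spec validates its inputs", {
  expect_error(fixture_spec(1), class = "tcrsplit_precondition_error")
  expect_error(fixture_spec(10, length_range = c(3, 11)),
               class = "tcrsplit_precondition_error")
  expect_error(fixture_spec(10, jitter_sd = -1),
               class = "tcrsplit_precondition_error")
})

test_that("synthetic structures satisfy the backbone invariants", {
  spec <- fixture_spec(n_peptides = 20, seed = 11)
  peps <- generate_peptides(spec)
  structs <- generate_structures(peps$peptide, spec)
  for (p in peps$peptide) {
    ps <- structs[[p]]
    expect_equal(nrow(ps$ca), nchar(p))
    step <- sqrt(rowSums(diff(ps$ca)^2))
    expect_true(all(step > 2.0 & step < 4.5))
  }
})

test_that("zero jitter gives identical geometry for same-length peptides", {
  spec <- fixture_spec(n_peptides = 2, jitter_sd = 0, seed = 1)
  structs <- generate_structures(c("ACDEFGHIK", "WYVSTRQPN"), spec)
  expect_equal(ca_rmsd(structs[[1]], structs[[2]]), 0, tolerance = 1e-9)

  spec2 <- fixture_spec(n_peptides = 2, jitter_sd = 0.5, seed = 2)
  s1 <- generate_structures("ACDEFGHIK", spec2)[[1]]
  spec3 <- fixture_spec(n_peptides = 2, jitter_sd = 0.5, seed = 3)
  s2 <- generate_structures("ACDEFGHIK", spec3)[[1]]
  expect_gt(ca_rmsd(s1, s2), 0)
})

test_that("mean pairwise RMSD grows with the jitter level", {
  seqs <- replicate(10, random_peptide(9))
  ## jitter levels kept inside the range where the 2.0-4.5 A consecutive
  ## spacing invariant remains satisfiable
  means <- vapply(c(0.05, 0.15, 0.3), function(sd) {
    vals <- vapply(1:10, function(rep) {
      spec <- fixture_spec(n_peptides = 2, jitter_sd = sd,
                           seed = 100L + rep)
      st <- generate_structures(seqs[1:4], spec)
      dm <- peptide_distances(seqs[1:4], "rmsd", st)
      mean(dm$values[upper.tri(dm$values)])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("interaction generation respects counts and label models", {
  spec <- fixture_spec(n_peptides = 50, seed = 12)
  peps <- generate_peptides(spec)
  ds <- generate_interactions(peps, spec)
  got <- peptide_counts(ds)
  want <- setNames(peps$count, peps$peptide)
  expect_equal(got$n, unname(want[got$peptide]))
  expect_true(all(ds$label %in% 0:1))
  expect_equal(anyDuplicated(paste(ds$peptide, ds$cdr3b, ds$label)), 0L)
})

test_that("random labels are balanced at large n", {
  spec <- fixture_spec(n_peptides = 1200, seed = 13,
                       count_distribution = "uniform",
                       uniform_count = 10L)
  ds <- generate_interactions(generate_peptides(spec), spec)
  expect_gte(nrow(ds), 10000L)
  expect_lt(abs(mean(ds$label) - 0.5), 0.02)
})

test_that("peptide-keyed labels track the latent propensities", {
  spec <- fixture_spec(n_peptides = 60, seed = 14,
                       count_distribution = "uniform",
                       uniform_count = 30L,
                       label_model = "peptide_keyed")
  ds <- generate_interactions(generate_peptides(spec), spec)
  prop <- attr(ds, "propensity")
  rates <- ds |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(rate = mean(label), .groups = "drop") |>
    dplyr::left_join(prop, by = "peptide")
  expect_gt(cor(rates$rate, rates$propensity, method = "spearman"), 0.8)
})

test_that("a written fixture feeds the whole pipeline end to end", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_peptides = 15, seed = 15)
  paths <- generate_fixture(spec, dir)
  ds <- read_interaction_table(paths$interactions)
  peps <- unique(ds$peptide)
  structs <- read_structure_dir(peps, paths$structure_dir)
  for (metric in c("levenshtein", "blosum", "rmsd")) {
    dm <- peptide_distances(peps, metric, structures = structs)
    sa <- split_distance(ds, dm,
                         split_config(band = c(0, 100), min_count = 1,
                                      seed = 2))
    expect_s3_class(sa, "split_assignment")
    expect_equal(nrow(sa), nrow(ds))
  }
})
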