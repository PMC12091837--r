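make_ds <- function(n_peptides = 30, seed = 1,
                    label_model = "random") {
  spec <- fixture_spec(n_peptides = n_peptides, seed = seed,
                       label_model = label_model)
  peps <- generate_peptides(spec)
  list(ds = generate_interactions(peps, spec),
       dm = peptide_distances(peps$peptide, "levenshtein"),
       peps = peps)
}

test_that("split_config validates ratios, band and counts", {
  expect_error(split_config(ratios = c(0.5, 0.4, 0.2)),
               class = "tcrsplit_precondition_error")
  expect_error(split_config(band = c(50, 40)),
               class = "tcrsplit_precondition_error")
  expect_error(split_config(band = c(-5, 50)),
               class = "tcrsplit_precondition_error")
  expect_error(split_config(min_count = 10, max_count = 5),
               class = "tcrsplit_precondition_error")
})

test_that("percentile bounds use linear interpolation between ranks", {
  agg <- tibble::tibble(peptide = paste0("P", 1:100),
                        distance = as.numeric(1:100))
  expect_equal(percentile_bounds(agg, c(0, 100)),
               c(d_l = 1, d_u = 100))
  cons <- tibble::tibble(peptide = paste0("P", 1:5), distance = rep(3, 5))
  expect_equal(percentile_bounds(cons, c(10, 60)), c(d_l = 3, d_u = 3))
  ## hand interpolation oracle on a small vector
  small <- tibble::tibble(peptide = paste0("P", 1:4),
                          distance = c(0, 10, 20, 30))
  b <- percentile_bounds(small, c(0, 33))
  x <- sort(small$distance)
  h <- (4 - 1) * 0.33
  expect_equal(unname(b),
               c(x[1], x[floor(h) + 1] + (h - floor(h)) *
                   (x[floor(h) + 2] - x[floor(h) + 1])))
})

test_that("eligibility filters by band and record counts", {
  agg <- tibble::tibble(peptide = c("A", "B", "C", "D"),
                        distance = c(1, 5, 9, 5))
  counts <- tibble::tibble(peptide = c("A", "B", "C", "D"),
                           n = c(10L, 3L, 10L, 10L))
  got <- eligible_peptides(agg, c(d_l = 4, d_u = 9), counts,
                           min_count = 5, max_count = 100)
  expect_setequal(got, c("C", "D"))   # A out of band, B below min_count
})

test_that("eligibility equals brute-force filtering on random instances", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      n <- 50
      agg <- tibble::tibble(peptide = paste0("P", 1:n),
                            distance = runif(n, 0, 10))
      counts <- tibble::tibble(peptide = paste0("P", 1:n),
                               n = sample(1:30, n, replace = TRUE))
      bounds <- sort(runif(2, 0, 10))
      got <- eligible_peptides(agg, bounds, counts, 5, 20)
      want <- agg$peptide[agg$distance >= bounds[1] &
                            agg$distance <= bounds[2] &
                            counts$n >= 5 & counts$n <= 20]
      expect_setequal(got, want)
    }
  })
})

test_that("random split cuts exactly at the ratio boundaries", {
  ds <- as_interactions(tibble::tibble(
    peptide = replicate(100, random_peptide(9)),
    cdr3b = replicate(100, random_peptide(13))))
  sa <- split_random(ds, split_config(seed = 2))
  expect_equal(unname(split_sizes(sa)[c("train", "validation", "test")]),
               c(90L, 5L, 5L))
  expect_equal(nrow(sa), 100L)
  ## partition: every record appears exactly once
  expect_identical(sort(paste(sa$peptide, sa$cdr3b)),
                   sort(paste(ds$peptide, ds$cdr3b)))
  expect_identical(split_random(ds, split_config(seed = 2))$split,
                   sa$split)
  expect_false(identical(split_random(ds, split_config(seed = 3))$split,
                         sa$split))
})

test_that("hard split keeps peptide sets disjoint and whole", {
  x <- make_ds(40, seed = 8)
  sa <- split_hard(x$ds, split_config(seed = 1))
  sp <- split(sa$peptide, sa$split)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
  ## atomicity: all records of a peptide share one split
  per_pep <- tapply(as.character(sa$split), sa$peptide,
                    function(s) length(unique(s)))
  expect_true(all(per_pep == 1L))
  ## minimal case: 3 peptides, one each
  tiny <- as_interactions(tibble::tibble(
    peptide = c("AAAAA", "CCCCC", "DDDDD"),
    cdr3b = c("CAF", "CAG", "CAH")))
  sa3 <- split_hard(tiny, split_config(ratios = c(1, 1, 1) / 3, seed = 4))
  expect_equal(unname(split_sizes(sa3)), c(1L, 1L, 1L))
})

test_that("hard split test fraction is near the 5% target on average", {
  ## sized so that no single peptide exceeds the 2-point tolerance:
  ## whole-peptide draws overshoot the budget by at most one peptide
  spec <- fixture_spec(n_peptides = 800, seed = 3)
  peps <- generate_peptides(spec)
  ds <- generate_interactions(peps, spec)
  fracs <- vapply(1:100, function(s) {
    sa <- split_hard(ds, split_config(seed = s))
    unname(split_sizes(sa)[["test"]]) / nrow(ds)
  }, numeric(1))
  expect_gt(mean(fracs), 0.03)
  expect_lt(mean(fracs), 0.07)
})

test_that("distance split respects band containment and disjointness", {
  x <- make_ds(60, seed = 5)
  cfg <- split_config(band = c(25, 75), min_count = 1, seed = 9)
  sa <- split_distance(x$ds, x$dm, cfg)
  agg <- aggregate_distances(x$dm, "median")
  bounds <- percentile_bounds(agg, cfg$band)
  held <- unique(sa$peptide[sa$split != "train"])
  dist_of <- setNames(agg$distance, agg$peptide)
  expect_true(all(dist_of[held] >= bounds[1] &
                    dist_of[held] <= bounds[2]))
  sp <- split(sa$peptide, sa$split)
  expect_length(intersect(sp$train, c(sp$test, sp$validation)), 0L)
  ## determinism
  expect_identical(split_distance(x$ds, x$dm, cfg)$split, sa$split)
})

test_that("a single huge eligible peptide overshoots the budget atomically", {
  ds <- as_interactions(tibble::tibble(
    peptide = c(rep("AAAAAAAAA", 10), "CCCCCCCCC", "DDDDDDDDD",
                "EEEEEEEEE"),
    cdr3b = c(replicate(10, random_peptide(12)), "CAF", "CAG", "CAH")))
  dm <- peptide_distances(unique(ds$peptide), "levenshtein")
  ## only the 10-record peptide is eligible (min_count 5); test budget ~1
  cfg <- split_config(ratios = c(0.8, 0.1, 0.1), min_count = 5, seed = 1)
  expect_error(split_distance(ds, dm, cfg),
               class = "tcrsplit_infeasible_error")
  ## with validation drawing relaxed via min_count 1 the peptide moves whole
  cfg2 <- split_config(ratios = c(0.8, 0.1, 0.1), min_count = 1, seed = 1)
  sa <- split_distance(ds, dm, cfg2)
  test_peps <- unique(sa$peptide[sa$split == "test"])
  per_pep <- tapply(as.character(sa$split), sa$peptide,
                    function(s) length(unique(s)))
  expect_true(all(per_pep == 1L))
  expect_gte(unname(split_sizes(sa)[["test"]]),
             attr(sa, "budgets")[["test"]])
})

test_that("an empty eligible pool is an infeasibility error", {
  x <- make_ds(30, seed = 6)
  expect_error(
    split_distance(x$ds, x$dm,
                   split_config(band = c(0, 100), min_count = 4000)),
    class = "tcrsplit_infeasible_error")
})

test_that("higher bands give larger train-to-test cross distances", {
  spec <- fixture_spec(n_peptides = 200, seed = 12)
  peps <- generate_peptides(spec)
  ds <- generate_interactions(peps, spec)
  dm <- peptide_distances(peps$peptide, "levenshtein")
  lo <- split_distance(ds, dm, split_config(band = c(0, 33), seed = 2))
  hi <- split_distance(ds, dm, split_config(band = c(66, 100), seed = 2))
  expect_lt(cross_split_distance(lo, dm), cross_split_distance(hi, dm))
})

test_that("split assignments serialize with a complete manifest", {
  x <- make_ds(30, seed = 7)
  sa <- split_distance(x$ds, x$dm,
                       split_config(band = c(0, 100), min_count = 1,
                                    seed = 3))
  dir <- withr::local_tempdir()
  write_split(sa, dir)
  expect_setequal(list.files(dir),
                  c("train.tsv", "validation.tsv", "test.tsv",
                    "manifest.json"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$method, "distance")
  expect_equal(man$seed, 3)
  expect_equal(man$realized_counts$test,
               unname(split_sizes(sa)[["test"]]))
  back <- read_interaction_table(file.path(dir, "train.tsv"))
  expect_equal(nrow(back), unname(split_sizes(sa)[["train"]]))
})
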