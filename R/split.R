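#' Split configuration
#'
#' Parameters shared by the three splitting strategies. The ratios follow
#' the common 90-5-5 train/validation/test convention; the percentile band
#' and the count limits only matter for the Distance Split.
#'
#' @param ratios Length-3 positive numeric vector (train, validation, test)
#'   summing to 1.
#' @param band Percentile band `c(lower, upper)` with
#'   `0 <= lower < upper <= 100`, taken over the cumulative distribution of
#'   the aggregated peptide-peptide distances.
#' @param min_count,max_count Only peptides whose record count lies in
#'   `[min_count, max_count]` are eligible for test/validation under the
#'   Distance Split; this bounds how much a single very frequent (or very
#'   rare) peptide can dominate those sets.
#' @param seed Integer seed driving all random draws of a split.
#' @param aggregator Row-wise aggregator of the distance matrix, see
#'   [aggregate_distances()].
#' @return An object of class `split_config`.
#' @export
split_config <- function(ratios = c(train = 0.90, validation = 0.05,
                                    test = 0.05),
                         band = c(0, 100), min_count = 5L, max_count = 5000L,
                         seed = 1L,
                         aggregator = c("median", "mean", "min")) {
  aggregator <- arg_match(aggregator)
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must be 3 positive numbers summing to 1",
          class = "tcrsplit_precondition_error")
  }
  band <- as.numeric(band)
  if (length(band) != 2L || band[[1L]] < 0 || band[[2L]] > 100 ||
      band[[1L]] >= band[[2L]]) {
    abort("`band` must satisfy 0 <= lower < upper <= 100",
          class = "tcrsplit_precondition_error")
  }
  if (!(min_count >= 1L && min_count <= max_count)) {
    abort("need 1 <= min_count <= max_count",
          class = "tcrsplit_precondition_error")
  }
  structure(list(ratios = setNames(ratios, c("train", "validation", "test")),
                 band = band, min_count = as.integer(min_count),
                 max_count = as.numeric(max_count), seed = as.integer(seed),
                 aggregator = aggregator),
            class = "split_config")
}

split_budgets <- function(n, ratios) {
  n_test <- round(ratios[["test"]] * n)
  n_val <- round(ratios[["validation"]] * n)
  c(train = n - n_val - n_test, validation = n_val, test = n_test)
}

#' Percentile bounds of an aggregated distance vector
#'
#' Converts a percentile band into realized distance bounds `(d_l, d_u)`
#' using linear interpolation between closest ranks
#' (`stats::quantile(type = 7)`).
#'
#' @param agg Tibble from [aggregate_distances()].
#' @param band Percentile pair `c(lower, upper)`.
#' @return Named numeric vector `c(d_l = , d_u = )`.
#' @export
percentile_bounds <- function(agg, band) {
  band <- as.numeric(band)
  if (length(band) != 2L || band[[1L]] < 0 || band[[2L]] > 100 ||
      band[[1L]] >= band[[2L]]) {
    abort("`band` must satisfy 0 <= lower < upper <= 100",
          class = "tcrsplit_precondition_error")
  }
  if (nrow(agg) < 2L) {
    abort("need at least 2 peptides", class = "tcrsplit_precondition_error")
  }
  q <- quantile(agg$distance, probs = band / 100, type = 7, names = FALSE)
  c(d_l = q[[1L]], d_u = q[[2L]])
}

#' Peptides eligible for the Distance Split test/validation pool
#'
#' @param agg Tibble from [aggregate_distances()].
#' @param bounds Realized distance bounds from [percentile_bounds()].
#' @param counts Tibble with columns `peptide`, `n` covering every peptide
#'   in `agg` (peptides without records count as 0).
#' @param min_count,max_count Inclusive record-count limits.
#' @return Character vector of eligible peptides (possibly empty).
#' @export
eligible_peptides <- function(agg, bounds, counts, min_count = 5L,
                              max_count = 5000L) {
  cnt <- left_join(agg, counts, by = "peptide")
  cnt$n[is.na(cnt$n)] <- 0L
  ok <- cnt$distance >= bounds[[1L]] & cnt$distance <= bounds[[2L]] &
    cnt$n >= min_count & cnt$n <= max_count
  cnt$peptide[ok]
}

new_split_assignment <- function(records, split, method, cfg,
                                 bounds = c(d_l = NA_real_, d_u = NA_real_),
                                 metric = NA_character_) {
  records$split <- factor(split, levels = c("train", "validation", "test"))
  out <- as_tibble(records)
  attr(out, "method") <- method
  attr(out, "config") <- cfg
  attr(out, "budgets") <- split_budgets(nrow(records), cfg$ratios)
  attr(out, "bounds") <- bounds
  attr(out, "metric") <- metric
  class(out) <- c("split_assignment", class(out))
  out
}

#' Sizes of a split assignment
#'
#' @param sa A split assignment.
#' @return Named integer vector of record counts per split.
#' @export
split_sizes <- function(sa) {
  tab <- table(sa$split)
  setNames(as.integer(tab), names(tab))
}

#' Random Split (record-level)
#'
#' Permutes the records uniformly and cuts at the ratio boundaries. The
#' same peptide (and the same CDR3-beta) may land in several splits, so a
#' predictor can score test records for peptides it has memorised -- the
#' leakage the Hard and Distance Splits are designed to remove.
#'
#' @param ds Interaction tibble.
#' @param cfg [split_config()].
#' @return A `split_assignment`: `ds` with a `split` factor column and the
#'   split metadata in attributes.
#' @export
split_random <- function(ds, cfg = split_config()) {
  ds <- as_tibble(ds)
  n <- nrow(ds)
  if (n < 3L) {
    abort("need at least 3 records", class = "tcrsplit_precondition_error")
  }
  budgets <- split_budgets(n, cfg$ratios)
  perm <- withr::with_seed(cfg$seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(budgets[["train"]])]] <- "train"
  split[perm[budgets[["train"]] + seq_len(budgets[["validation"]])]] <-
    "validation"
  split[perm[n - seq_len(budgets[["test"]]) + 1L]] <- "test"
  new_split_assignment(ds, split, "random", cfg)
}

## Draw whole peptides uniformly from `pool` until `budget` records are
## reached (the last peptide may overshoot; it moves atomically).
draw_peptides_to_budget <- function(pool, counts_map, budget, what) {
  chosen <- character(0)
  size <- 0L
  while (size < budget) {
    if (length(pool) == 0L) {
      abort(sprintf(
        "eligible peptide pool exhausted while filling the %s set (%d of %d records placed)",
        what, size, budget), class = "tcrsplit_infeasible_error")
    }
    pick <- pool[[sample.int(length(pool), 1L)]]
    pool <- setdiff(pool, pick)
    chosen <- c(chosen, pick)
    size <- size + counts_map[[pick]]
  }
  list(chosen = chosen, pool = pool, size = size)
}

#' Hard Split (peptide-disjoint)
#'
#' Samples whole peptides uniformly at random into the test and then the
#' validation set until each budget is met, moving all of a peptide's
#' records together; remaining peptides form the training set. Test
#' peptides are therefore never observed at training time.
#'
#' @inheritParams split_random
#' @return A `split_assignment`.
#' @export
split_hard <- function(ds, cfg = split_config()) {
  ds <- as_tibble(ds)
  peps <- unique(ds$peptide)
  if (length(peps) < 3L) {
    abort("need at least 3 unique peptides",
          class = "tcrsplit_precondition_error")
  }
  budgets <- split_budgets(nrow(ds), cfg$ratios)
  counts <- peptide_counts(ds)
  counts_map <- setNames(as.list(counts$n), counts$peptide)
  picks <- withr::with_seed(cfg$seed, {
    te <- draw_peptides_to_budget(peps, counts_map, budgets[["test"]],
                                  "test")
    va <- draw_peptides_to_budget(te$pool, counts_map,
                                  budgets[["validation"]], "validation")
    list(test = te$chosen, validation = va$chosen)
  })
  split <- ifelse(ds$peptide %in% picks$test, "test",
                  ifelse(ds$peptide %in% picks$validation, "validation",
                         "train"))
  new_split_assignment(ds, split, "hard", cfg)
}

#' Distance Split (peptide-disjoint, distance-band controlled)
#'
#' Like the Hard Split, but test and validation peptides are drawn only
#' from the *eligible* pool: peptides whose aggregated distance to all
#' other peptides falls inside the percentile band of `cfg$band`, and whose
#' record count lies within `[min_count, max_count]`. Sampling a high band
#' yields test peptides far (under the chosen metric) from the training
#' ones, i.e. a harder out-of-distribution task; a low band yields an
#' easier one.
#'
#' The procedure: aggregate the distance matrix row-wise (median by
#' default), turn the percentile band into realized distance bounds
#' `(d_l, d_u)`, filter to eligible peptides, then repeatedly draw an
#' eligible peptide uniformly at random and move all its records to the
#' test set until the test budget is reached; repeat for validation from
#' the remaining eligible peptides; all remaining peptides train.
#'
#' @inheritParams split_random
#' @param dm A `peptide_dist` covering every peptide in `ds`.
#' @return A `split_assignment` whose attributes record the realized
#'   bounds, budgets, metric and seed.
#' @export
split_distance <- function(ds, dm, cfg = split_config()) {
  ds <- as_tibble(ds)
  stopifnot(inherits(dm, "peptide_dist"))
  missing <- setdiff(unique(ds$peptide), dm$peptides)
  if (length(missing) > 0L) {
    abort(paste0("peptides absent from the distance matrix: ",
                 paste(utils::head(missing, 5L), collapse = ", ")),
          class = "tcrsplit_precondition_error")
  }
  agg <- aggregate_distances(dm, cfg$aggregator)
  bounds <- percentile_bounds(agg, cfg$band)
  counts <- peptide_counts(ds)
  pool <- eligible_peptides(agg, bounds, counts, cfg$min_count,
                            cfg$max_count)
  pool <- intersect(pool, unique(ds$peptide))
  if (length(pool) == 0L) {
    abort("no eligible peptides in the requested band / count range",
          class = "tcrsplit_infeasible_error")
  }
  budgets <- split_budgets(nrow(ds), cfg$ratios)
  counts_map <- setNames(as.list(counts$n), counts$peptide)
  picks <- withr::with_seed(cfg$seed, {
    te <- draw_peptides_to_budget(pool, counts_map, budgets[["test"]],
                                  "test")
    va <- draw_peptides_to_budget(te$pool, counts_map,
                                  budgets[["validation"]], "validation")
    list(test = te$chosen, validation = va$chosen)
  })
  split <- ifelse(ds$peptide %in% picks$test, "test",
                  ifelse(ds$peptide %in% picks$validation, "validation",
                         "train"))
  new_split_assignment(ds, split, "distance", cfg, bounds = bounds,
                       metric = dm$metric)
}

#' Peptide-level cross-split distance summary
#'
#' Summarises the distances between the peptides of two splits (by default
#' the median train-to-test distance), read off the distance matrix. This
#' is the quantity the Distance Split bands control.
#'
#' @param sa A `split_assignment`.
#' @param dm A `peptide_dist` covering the peptides of both splits.
#' @param from,to Split names.
#' @param stat Summary function (default [median()]).
#' @return A scalar.
#' @export
cross_split_distance <- function(sa, dm, from = "train", to = "test",
                                 stat = median) {
  pf <- intersect(unique(sa$peptide[sa$split == from]), dm$peptides)
  pt <- intersect(unique(sa$peptide[sa$split == to]), dm$peptides)
  if (length(pf) == 0L || length(pt) == 0L) return(NA_real_)
  stat(dm$values[pf, pt, drop = FALSE])
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment> method =", attr(x, "method"),
      "| seed =", attr(x, "config")$seed, "\n")
  print(split_sizes(x))
  b <- attr(x, "bounds")
  if (!is.na(b[[1L]])) {
    cat(sprintf("band %s-%s -> bounds [%.4g, %.4g] (%s)\n",
                attr(x, "config")$band[[1L]], attr(x, "config")$band[[2L]],
                b[[1L]], b[[2L]], attr(x, "metric")))
  }
  invisible(x)
}

#' Serialize a split assignment
#'
#' Writes one canonical record table per split (`train.tsv`,
#' `validation.tsv`, `test.tsv`) plus a `manifest.json` with the method,
#' band, realized bounds, budgets, realized counts, aggregator, metric and
#' seed.
#'
#' @param sa A `split_assignment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(sa, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c("train", "validation", "test")) {
    write_interaction_table(sa[sa$split == s, , drop = FALSE],
                            file.path(dir, paste0(s, ".tsv")))
  }
  cfg <- attr(sa, "config")
  manifest <- list(
    method = attr(sa, "method"),
    metric = attr(sa, "metric"),
    band = cfg$band,
    bounds = as.list(attr(sa, "bounds")),
    budgets = as.list(attr(sa, "budgets")),
    realized_counts = as.list(split_sizes(sa)),
    ratios = as.list(cfg$ratios),
    min_count = cfg$min_count, max_count = cfg$max_count,
    aggregator = cfg$aggregator, seed = cfg$seed,
    package = "tcrsplit",
    version = as.character(packageVersion("tcrsplit")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
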