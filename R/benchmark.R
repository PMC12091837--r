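#' Peptide-memorization reference predictor
#'
#' Scores a (peptide, cdr3b) pair by the empirical positive rate of its
#' peptide among the training records; an unseen peptide scores 0.5. This
#' deliberately simple predictor captures exactly the leakage the splits
#' differ on: it is informative whenever test peptides were seen at
#' training time (Random Split) and uninformative by construction under
#' peptide-disjoint splits (Hard/Distance Split), where every test score is
#' the 0.5 fallback.
#'
#' @param train Interaction tibble of training records.
#' @return A scorer: `function(newdata)` returning scores in \[0, 1\].
#' @export
memorization_predictor <- function(train) {
  if (nrow(train) == 0L) {
    abort("training set is empty", class = "tcrsplit_precondition_error")
  }
  rates <- train %>%
    group_by(.data$peptide) %>%
    summarise(rate = mean(.data$label), .groups = "drop")
  function(newdata) {
    s <- left_join(as_tibble(newdata)["peptide"], rates, by = "peptide")$rate
    s[is.na(s)] <- 0.5
    s
  }
}

#' Uniform-random reference predictor
#'
#' @param train Interaction tibble (ignored).
#' @return A scorer returning i.i.d. uniform scores.
#' @export
random_predictor <- function(train) {
  function(newdata) runif(nrow(newdata))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length",
          class = "tcrsplit_precondition_error")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute AUROC",
          class = "tcrsplit_undefined_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Standard benchmark split plan
#'
#' One Random Split, one Hard Split, and one Distance Split per metric and
#' percentile band (defaults: (0,33), (33,66), (66,100) -- thirds of the
#' cumulative aggregated-distance distribution).
#'
#' @param metrics Character vector of metrics with available distance
#'   matrices.
#' @param bands List of percentile bands.
#' @param include_random,include_hard Include the baselines.
#' @return Tibble with columns `split_label`, `method`, `metric`,
#'   `band_lower`, `band_upper`, `band_index`.
#' @export
benchmark_splits <- function(metrics = "levenshtein",
                             bands = list(c(0, 33), c(33, 66), c(66, 100)),
                             include_random = TRUE, include_hard = TRUE) {
  base <- list()
  if (include_random) {
    base <- c(base, list(tibble(split_label = "RS", method = "random",
                                metric = NA_character_,
                                band_lower = NA_real_, band_upper = NA_real_,
                                band_index = NA_integer_)))
  }
  if (include_hard) {
    base <- c(base, list(tibble(split_label = "HS", method = "hard",
                                metric = NA_character_,
                                band_lower = NA_real_, band_upper = NA_real_,
                                band_index = NA_integer_)))
  }
  ds <- lapply(metrics, function(m) {
    tibble(split_label = sprintf("DS-%s-(%g,%g)", m,
                                 vapply(bands, `[[`, 0, 1L),
                                 vapply(bands, `[[`, 0, 2L)),
           method = "distance", metric = m,
           band_lower = vapply(bands, `[[`, 0, 1L),
           band_upper = vapply(bands, `[[`, 0, 2L),
           band_index = seq_along(bands))
  })
  bind_rows(c(base, ds))
}

#' Run the split benchmark
#'
#' For every split plan row and every seed: build the split, train the
#' predictor on the training records, score the test records, and record
#' the pooled test AUROC together with the median train-to-test peptide
#' distance. Summaries are the per-split mean with a normal-approximation
#' 95% confidence interval over seeds, and, per metric, the Spearman rank
#' correlation between the band index and the AUROC across the Distance
#' Split rows (exact p-value for <= 10 points and no ties, asymptotic
#' otherwise).
#'
#' @param ds Interaction tibble.
#' @param matrices Named list of `peptide_dist` objects, indexed by metric.
#' @param splits Split plan tibble from [benchmark_splits()].
#' @param seeds Integer vector of seeds (the repetition protocol; 5 by
#'   default).
#' @param predictor Predictor factory, e.g. [memorization_predictor()].
#' @param cfg Base [split_config()]; its band/seed fields are overridden
#'   per run.
#' @return A `tcr_benchmark` object: list with tibbles `results` (one row
#'   per split x seed), `summary` and `trend`.
#' @export
run_benchmark <- function(ds, matrices,
                          splits = benchmark_splits(names(matrices)),
                          seeds = 1:5,
                          predictor = memorization_predictor,
                          cfg = split_config()) {
  ds <- as_tibble(ds)
  ref_metric <- names(matrices)[[1L]]
  rows <- list()
  for (k in seq_len(nrow(splits))) {
    sp <- splits[k, ]
    metric <- if (is.na(sp$metric)) ref_metric else sp$metric
    for (seed in seeds) {
      run_cfg <- cfg
      run_cfg$seed <- as.integer(seed)
      if (sp$method == "distance") {
        run_cfg$band <- c(sp$band_lower, sp$band_upper)
      }
      sa <- switch(sp$method,
                   random = split_random(ds, run_cfg),
                   hard = split_hard(ds, run_cfg),
                   distance = split_distance(ds, matrices[[metric]],
                                             run_cfg))
      train <- sa[sa$split == "train", , drop = FALSE]
      test <- sa[sa$split == "test", , drop = FALSE]
      scorer <- predictor(train)
      scores <- withr::with_seed(seed + 10000L, scorer(test))
      rows[[length(rows) + 1L]] <- tibble(
        split_label = sp$split_label, method = sp$method, metric = metric,
        band_index = sp$band_index, seed = as.integer(seed),
        auroc = auroc(scores, test$label), n_test = nrow(test),
        cross_split_median_distance =
          cross_split_distance(sa, matrices[[metric]]))
    }
  }
  results <- bind_rows(rows)

  summary <- results %>%
    group_by(.data$split_label, .data$method, .data$metric,
             .data$band_index) %>%
    summarise(mean_auroc = mean(.data$auroc),
              sd_auroc = sd(.data$auroc),
              n_seeds = dplyr::n(),
              mean_cross_distance =
                mean(.data$cross_split_median_distance),
              .groups = "drop") %>%
    mutate(ci_lo = .data$mean_auroc -
             1.96 * .data$sd_auroc / sqrt(.data$n_seeds),
           ci_hi = .data$mean_auroc +
             1.96 * .data$sd_auroc / sqrt(.data$n_seeds))

  ds_rows <- filter(results, .data$method == "distance")
  trend <- if (nrow(ds_rows) == 0L) {
    tibble(metric = character(), rho = numeric(), p_value = numeric(),
           n_points = integer())
  } else {
    ds_rows %>%
      group_by(.data$metric) %>%
      summarise(spearman_trend(.data$band_index, .data$auroc),
                .groups = "drop")
  }

  structure(list(results = results, summary = summary, trend = trend),
            class = "tcr_benchmark")
}

spearman_trend <- function(band_index, auroc_values) {
  n <- length(auroc_values)
  ## the correlation is undefined when either variable is constant (e.g.
  ## a predictor whose AUROC is identically 0.5 on peptide-disjoint splits)
  if (n < 3L || sd(auroc_values) == 0 || sd(band_index) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n_points = n))
  }
  exact <- n <= 10L && !anyDuplicated(auroc_values)
  ct <- suppressWarnings(
    cor.test(band_index, auroc_values, method = "spearman", exact = exact))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_points = n)
}

#' @export
print.tcr_benchmark <- function(x, ...) {
  cat("<tcr_benchmark>", nrow(x$results), "runs\n")
  print(as.data.frame(x$summary[, c("split_label", "mean_auroc",
                                    "ci_lo", "ci_hi")]), digits = 3)
  invisible(x)
}

#' Serialize benchmark results
#'
#' Writes a tidy per-run table (`results.tsv`, one row per split x seed)
#' and a JSON trend summary (`trend.json`).
#'
#' @param bm A `tcr_benchmark`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bm$results, file.path(dir, "results.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(summary = bm$summary, trend = bm$trend,
         package = "tcrsplit",
         version = as.character(packageVersion("tcrsplit"))),
    file.path(dir, "trend.json"), auto_unbox = TRUE, pretty = TRUE,
    dataframe = "rows")
  invisible(dir)
}
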