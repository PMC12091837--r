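#' Pairwise peptide distance matrix
#'
#' Computes the symmetric matrix of pairwise distances between unique
#' peptides under one of three metrics:
#'
#' * `"levenshtein"` -- unit-cost edit distance between sequences;
#' * `"blosum"` -- global-alignment score distance
#'   `S(a,a) + S(b,b) - 2 S(a,b)` (see [blosum_distance()]);
#' * `"rmsd"` -- C-alpha RMSD between structures after alignment-based
#'   residue pairing and Kabsch superposition with outlier rejection
#'   (see [ca_rmsd()]); requires a structure for every peptide.
#'
#' @param peptides Character vector of unique peptide sequences (n >= 2).
#' @param metric One of `"levenshtein"`, `"blosum"`, `"rmsd"`.
#' @param structures Named list of [peptide_structure()] (required for
#'   `metric = "rmsd"`), indexed by peptide sequence.
#' @param params [alignment_params()] for the BLOSUM and RMSD metrics.
#' @param refine_cycles,outlier_cutoff RMSD refinement settings, see
#'   [ca_rmsd()].
#' @return A `peptide_dist` object: list with `peptides`, the n x n
#'   `values` matrix (zero diagonal, symmetric), `metric` and `params`.
#' @export
peptide_distances <- function(peptides,
                              metric = c("levenshtein", "blosum", "rmsd"),
                              structures = NULL,
                              params = alignment_params(),
                              refine_cycles = 5L, outlier_cutoff = 2.0) {
  metric <- arg_match(metric)
  peptides <- as.character(peptides)
  if (anyDuplicated(peptides) > 0L) {
    abort("`peptides` must be unique", class = "tcrsplit_precondition_error")
  }
  n <- length(peptides)
  if (n < 2L) {
    abort("need at least 2 peptides", class = "tcrsplit_precondition_error")
  }

  if (metric == "levenshtein") {
    values <- adist(peptides, peptides)
    storage.mode(values) <- "double"
  } else if (metric == "blosum") {
    mat <- substitution_matrix(params$matrix)
    idx <- lapply(peptides, seq_to_idx, mat = mat)
    scores <- .cpp_pairwise_scores(idx, mat, params$gap_open,
                                   params$gap_extend)
    self <- diag(scores)
    values <- pmax(outer(self, self, "+") - 2 * scores, 0)
    diag(values) <- 0
  } else {
    missing <- setdiff(peptides, names(structures))
    if (length(missing) > 0L) {
      abort(paste0("missing structures for: ",
                   paste(utils::head(missing, 5L), collapse = ", ")),
            class = "tcrsplit_missing_structure_error")
    }
    mat <- substitution_matrix(params$matrix)
    idx <- lapply(peptides, seq_to_idx, mat = mat)
    coords <- lapply(peptides, function(p) structures[[p]]$ca)
    values <- .cpp_rmsd_matrix(idx, coords, mat, params$gap_open,
                               params$gap_extend,
                               as.integer(refine_cycles), outlier_cutoff)
  }

  dimnames(values) <- list(peptides, peptides)
  structure(list(peptides = peptides, values = values, metric = metric,
                 params = params),
            class = "peptide_dist")
}

#' @export
print.peptide_dist <- function(x, ...) {
  cat("<peptide_dist> ", length(x$peptides), " peptides, metric = ",
      x$metric, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.peptide_dist <- function(x, ...) x$values

#' Row-wise aggregate of a distance matrix
#'
#' For every peptide, aggregates its distances to all *other* peptides
#' (the zero diagonal is excluded). The row-wise median is the quantity the
#' Distance Split bands are defined on; mean and min are alternatives (min
#' gives the most stringent notion of novelty).
#'
#' @param dm A `peptide_dist` from [peptide_distances()].
#' @param aggregator One of `"median"`, `"mean"`, `"min"`.
#' @return Tibble with columns `peptide` and `distance`, carrying the
#'   aggregator and metric as attributes.
#' @export
aggregate_distances <- function(dm, aggregator = c("median", "mean", "min")) {
  aggregator <- arg_match(aggregator)
  stopifnot(inherits(dm, "peptide_dist"))
  n <- length(dm$peptides)
  if (n < 2L) {
    abort("need at least 2 peptides", class = "tcrsplit_precondition_error")
  }
  fun <- switch(aggregator, median = median, mean = mean, min = min)
  vals <- vapply(seq_len(n), function(i) fun(dm$values[i, -i]), numeric(1))
  out <- tibble(peptide = dm$peptides, distance = vals)
  attr(out, "aggregator") <- aggregator
  attr(out, "metric") <- dm$metric
  out
}

#' Write / read a distance matrix
#'
#' The matrix is stored as a tab-separated square table with peptide labels
#' on both axes, plus a JSON sidecar (`<path>.json`) recording the metric,
#' alignment parameters and package version.
#'
#' @param dm A `peptide_dist`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as_tibble(dm$values, .name_repair = "minimal")
  names(df) <- dm$peptides
  df <- dplyr::bind_cols(tibble(peptide = dm$peptides), df)
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(metric = dm$metric,
               params = unclass(dm$params),
               package = "tcrsplit",
               version = as.character(packageVersion("tcrsplit")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  peptides <- df$peptide
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- list(peptides, peptides)
  meta_path <- paste0(path, ".json")
  metric <- "levenshtein"
  params <- alignment_params()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    metric <- meta$metric %||% metric
    if (!is.null(meta$params)) {
      params <- alignment_params(meta$params$matrix %||% "BLOSUM62",
                                 meta$params$gap_open %||% -10,
                                 meta$params$gap_extend %||% -1)
    }
  }
  structure(list(peptides = peptides, values = values, metric = metric,
                 params = params),
            class = "peptide_dist")
}
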