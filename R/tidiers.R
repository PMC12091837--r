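#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into long form
#'
#' @param x A `peptide_dist`.
#' @param upper_only Keep each unordered pair once (`i < j`).
#' @param ... Unused.
#' @return Tibble with columns `peptide_a`, `peptide_b`, `distance`,
#'   `metric`.
#' @export
tidy.peptide_dist <- function(x, upper_only = TRUE, ...) {
  n <- length(x$peptides)
  idx <- which(upper.tri(x$values) | (!upper_only & lower.tri(x$values)),
               arr.ind = TRUE)
  tibble(peptide_a = x$peptides[idx[, 1L]],
         peptide_b = x$peptides[idx[, 2L]],
         distance = x$values[idx],
         metric = x$metric)
}

#' @export
glance.peptide_dist <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble(metric = x$metric, n_peptides = length(x$peptides),
         mean = mean(off), median = median(off), sd = sd(off),
         min = min(off), max = max(off))
}

#' Tidy a split assignment
#'
#' @param x A `split_assignment`.
#' @param ... Unused.
#' @return One row per split: record/peptide/label counts and realized
#'   fraction.
#' @export
tidy.split_assignment <- function(x, ...) {
  as_tibble(x) %>%
    group_by(split = .data$split) %>%
    summarise(n_records = dplyr::n(),
              n_peptides = dplyr::n_distinct(.data$peptide),
              n_positive = sum(.data$label == 1L),
              n_negative = sum(.data$label == 0L),
              .groups = "drop") %>%
    mutate(fraction = .data$n_records / sum(.data$n_records))
}

#' @export
glance.split_assignment <- function(x, ...) {
  cfg <- attr(x, "config")
  b <- attr(x, "bounds")
  sizes <- split_sizes(x)
  tibble(method = attr(x, "method"), metric = attr(x, "metric"),
         band_lower = cfg$band[[1L]], band_upper = cfg$band[[2L]],
         d_l = b[[1L]], d_u = b[[2L]],
         n_train = sizes[["train"]], n_validation = sizes[["validation"]],
         n_test = sizes[["test"]], aggregator = cfg$aggregator,
         seed = cfg$seed)
}

#' @export
tidy.tcr_benchmark <- function(x, ...) x$results

#' @export
glance.tcr_benchmark <- function(x, ...) {
  if (nrow(x$trend) == 0L) {
    return(tibble(metric = character(), rho = numeric(),
                  p_value = numeric(), n_points = integer()))
  }
  x$trend
}
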