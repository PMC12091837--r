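#' Default VDJdb column mapping
#'
#' Maps the canonical schema roles of an interaction table onto the column
#' names found in VDJdb exports. Each role may list several candidate names;
#' the first one present in the file is used.
#'
#' @return Named list of character vectors, one entry per schema role.
#' @export
vdjdb_column_map <- function() {
  list(
    peptide    = c("antigen.epitope", "peptide"),
    cdr3b      = c("cdr3", "cdr3.beta", "cdr3b"),
    cdr3a      = c("cdr3.alpha", "cdr3a"),
    mhc_allele = c("mhc.a", "mhc_allele"),
    label      = c("label", "binder"),
    source     = "source"
  )
}

interaction_columns <- c("peptide", "cdr3b", "cdr3a", "mhc_allele",
                         "label", "source")

#' Coerce a data frame to a canonical interaction table
#'
#' Normalises peptide and CDR3-beta sequences to uppercase, fills in the
#' optional columns (`cdr3a`, `mhc_allele`, `label`, `source`) when absent,
#' drops rows whose peptide or CDR3-beta contains letters outside the 20
#' standard amino acids, and collapses duplicate (peptide, cdr3b, label)
#' rows so that repeated records cannot leak across later splits.
#'
#' @param x A data frame with at least `peptide` and `cdr3b` columns.
#' @return A tibble with columns `peptide`, `cdr3b`, `cdr3a`, `mhc_allele`,
#'   `label`, `source`. The number of rows dropped per reason is attached as
#'   the `drop_report` attribute (a tibble with columns `reason` and `n`).
#' @export
as_interactions <- function(x) {
  x <- as_tibble(x)
  for (col in c("peptide", "cdr3b")) {
    if (!col %in% names(x)) {
      abort(paste0("column `", col, "` is required"),
            class = "tcrsplit_schema_error")
    }
  }
  if (!"cdr3a" %in% names(x)) x$cdr3a <- NA_character_
  if (!"mhc_allele" %in% names(x)) x$mhc_allele <- NA_character_
  if (!"label" %in% names(x)) x$label <- 1L
  if (!"source" %in% names(x)) x$source <- "observed"

  x <- x %>%
    mutate(
      peptide = toupper(as.character(.data$peptide)),
      cdr3b   = toupper(as.character(.data$cdr3b)),
      cdr3a   = toupper(as.character(.data$cdr3a)),
      label   = coerce_binary_label(.data$label),
      source  = as.character(.data$source)
    )

  bad_alpha <- !grepl(AA20_REGEX, x$peptide) | !grepl(AA20_REGEX, x$cdr3b)
  bad_alpha[is.na(bad_alpha)] <- TRUE
  bad_label <- is.na(x$label)
  kept <- x[!bad_alpha & !bad_label, , drop = FALSE]

  n_before <- nrow(kept)
  kept <- distinct(kept, .data$peptide, .data$cdr3b, .data$label,
                   .keep_all = TRUE)
  report <- tibble(
    reason = c("invalid_alphabet", "invalid_label", "duplicate_triple"),
    n = c(sum(bad_alpha), sum(bad_label & !bad_alpha), n_before - nrow(kept))
  )
  out <- select(kept, all_of(interaction_columns))
  attr(out, "drop_report") <- report
  out
}

coerce_binary_label <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.character(label)) {
    lab <- tolower(label)
    out <- ifelse(lab %in% c("1", "true", "binding", "binder", "yes"), 1L,
           ifelse(lab %in% c("0", "false", "non-binding", "nonbinder", "no"), 0L,
                  NA_integer_))
    return(out)
  }
  out <- as.integer(label)
  out[!out %in% c(0L, 1L)] <- NA_integer_
  out
}

#' Read a VDJdb-style interaction table
#'
#' Reads a tab-separated table with a header row, maps its columns onto the
#' canonical schema via `column_map`, and validates the sequences (see
#' [as_interactions()]). Rows failing validation are dropped and counted in
#' the `drop_report` attribute of the result.
#'
#' @param path Path to a tab-separated file.
#' @param column_map Named list mapping schema roles (`peptide`, `cdr3b`,
#'   `cdr3a`, `mhc_allele`, `label`) to candidate column names; see
#'   [vdjdb_column_map()].
#' @return A canonical interaction tibble (see [as_interactions()]).
#' @export
read_interaction_table <- function(path, column_map = vdjdb_column_map()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tcrsplit_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) {
    abort("interaction table is empty", class = "tcrsplit_empty_error")
  }
  out <- tibble(.rows = nrow(raw))
  for (role in c("peptide", "cdr3b", "cdr3a", "mhc_allele", "label",
                 "source")) {
    candidates <- column_map[[role]] %||% character()
    hit <- candidates[candidates %in% names(raw)]
    if (length(hit) > 0L) {
      out[[role]] <- raw[[hit[[1L]]]]
    } else if (role %in% c("peptide", "cdr3b")) {
      abort(paste0("no column for role `", role, "` among: ",
                   paste(candidates, collapse = ", ")),
            class = "tcrsplit_schema_error")
    }
  }
  as_interactions(out)
}

#' Write a canonical interaction table
#'
#' @param ds Interaction tibble.
#' @param path Output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(ds, path) {
  readr::write_tsv(select(as_tibble(ds), all_of(interaction_columns)), path,
                   progress = FALSE)
  invisible(path)
}

#' Per-peptide record counts
#'
#' @param ds Interaction tibble.
#' @return Tibble with columns `peptide` and `n` (record multiplicity).
#' @export
peptide_counts <- function(ds) {
  count(as_tibble(ds), .data$peptide, name = "n")
}

#' Filter an interaction table
#'
#' Drops records missing required fields and, optionally, records whose MHC
#' allele does not match a glob pattern (e.g. `"HLA-A*"` keeps class I
#' HLA-A alleles only).
#'
#' @param ds Interaction tibble.
#' @param require_cdr3b,require_peptide Drop records with a missing/empty
#'   CDR3-beta (peptide) sequence.
#' @param mhc_pattern Optional glob pattern matched against `mhc_allele`.
#' @return Filtered interaction tibble (possibly empty).
#' @export
filter_interactions <- function(ds, require_cdr3b = TRUE,
                                require_peptide = TRUE, mhc_pattern = NULL) {
  ds <- as_tibble(ds)
  keep <- rep(TRUE, nrow(ds))
  if (require_peptide) {
    keep <- keep & !is.na(ds$peptide) & nzchar(ds$peptide)
  }
  if (require_cdr3b) {
    keep <- keep & !is.na(ds$cdr3b) & nzchar(ds$cdr3b)
  }
  if (!is.null(mhc_pattern)) {
    rx <- glob2rx(mhc_pattern)
    keep <- keep & !is.na(ds$mhc_allele) & grepl(rx, ds$mhc_allele)
  }
  ds[keep, , drop = FALSE]
}

#' Generate shuffled negative pairs
#'
#' Augments a table of binding records with non-binding records obtained by
#' shuffling: each negative is a (peptide, cdr3b) combination drawn from the
#' peptides and CDR3-beta sequences already present among the positives, but
#' not itself observed as a positive pair. This rests on the standard
#' assumption that a random TCR-peptide pairing is very unlikely to bind.
#'
#' Combinations are rejection-sampled against the positive set; if the
#' required number cannot be reached that way the remaining non-positive
#' combinations are enumerated exhaustively (feasible at the dataset sizes
#' this package targets), so the draw is exact.
#'
#' @param ds Interaction tibble containing only `label == 1` records.
#' @param n_negatives Number of negatives to generate; defaults to the
#'   number of positive records (a balanced dataset).
#' @param seed Integer seed; the same seed reproduces the same negatives.
#' @return `ds` with `n_negatives` appended rows having `label = 0` and
#'   `source = "shuffled"`.
#' @export
generate_negatives <- function(ds, n_negatives = nrow(ds), seed = 1L) {
  ds <- as_tibble(ds)
  if (any(ds$label != 1L)) {
    abort("`ds` must contain only positive (label == 1) records",
          class = "tcrsplit_precondition_error")
  }
  n_negatives <- as.integer(n_negatives)
  if (n_negatives < 0L) {
    abort("`n_negatives` must be non-negative",
          class = "tcrsplit_precondition_error")
  }
  if (n_negatives == 0L) return(ds)

  peps <- unique(ds$peptide)
  cdrs <- unique(ds$cdr3b)
  pos_keys <- unique(paste(ds$peptide, ds$cdr3b, sep = "\r"))
  n_total <- as.double(length(peps)) * length(cdrs)
  n_avail <- n_total - length(pos_keys)
  if (n_negatives > n_avail) {
    abort(sprintf(
      "requested %d negatives but only %.0f non-positive combinations exist",
      n_negatives, n_avail), class = "tcrsplit_infeasible_error")
  }

  draw <- withr::with_seed(seed, {
    got_p <- character(0)
    got_c <- character(0)
    seen <- pos_keys
    tries <- 0L
    while (length(got_p) < n_negatives && tries < 50L) {
      tries <- tries + 1L
      m <- 2L * (n_negatives - length(got_p))
      pi <- sample(peps, m, replace = TRUE)
      ci <- sample(cdrs, m, replace = TRUE)
      key <- paste(pi, ci, sep = "\r")
      ok <- !(key %in% seen) & !duplicated(key)
      got_p <- c(got_p, pi[ok])
      got_c <- c(got_c, ci[ok])
      seen <- c(seen, key[ok])
    }
    if (length(got_p) < n_negatives) {
      if (n_total > 2e6) {
        abort("rejection sampling failed and the combination space is too large to enumerate",
              class = "tcrsplit_infeasible_error")
      }
      all_keys <- as.vector(outer(peps, cdrs, paste, sep = "\r"))
      pool <- setdiff(all_keys, seen)
      extra <- sample(pool, n_negatives - length(got_p))
      parts <- strsplit(extra, "\r", fixed = TRUE)
      got_p <- c(got_p, vapply(parts, `[[`, "", 1L))
      got_c <- c(got_c, vapply(parts, `[[`, "", 2L))
    }
    list(p = got_p[seq_len(n_negatives)], c = got_c[seq_len(n_negatives)])
  })

  neg <- tibble(
    peptide = draw$p, cdr3b = draw$c,
    cdr3a = NA_character_, mhc_allele = NA_character_,
    label = 0L, source = "shuffled"
  )
  bind_rows(ds, neg)
}
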