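#' Alignment scoring parameters
#'
#' Parameters for Needleman-Wunsch global alignment with affine gap
#' penalties. A gap of length L scores `gap_open + (L - 1) * gap_extend`:
#' the first gapped position pays the opening penalty, each further
#' position the extension penalty.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Negative reals with
#'   `gap_open <= gap_extend < 0`. Defaults -10 / -1.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = -10,
                             gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    abort("need gap_open <= gap_extend < 0",
          class = "tcrsplit_precondition_error")
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_params")
}

#' Fetch a named substitution matrix
#'
#' @param name Matrix name, e.g. `"BLOSUM62"` or `"BLOSUM45"`.
#' @return The scoring matrix.
#' @export
substitution_matrix <- function(name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    abort(paste0("unknown substitution matrix: ", name),
          class = "tcrsplit_precondition_error")
  }
  get(name, envir = env)
}

## Residues -> 0-based row indices of the substitution matrix (for the
## C++ alignment kernel); unknown residues are an alphabet error.
seq_to_idx <- function(x, mat) {
  idx <- match(strsplit(x, "")[[1L]], rownames(mat)) - 1L
  if (anyNA(idx)) {
    bad <- setdiff(strsplit(x, "")[[1L]], rownames(mat))
    abort(paste0("residues absent from substitution matrix: ",
                 paste(unique(bad), collapse = ", ")),
          class = "tcrsplit_alphabet_error")
  }
  idx
}

check_alphabet <- function(x, mat) {
  letters_seen <- unique(strsplit(paste(x, collapse = ""), "")[[1L]])
  bad <- setdiff(letters_seen, rownames(mat))
  if (length(bad) > 0L) {
    abort(paste0("residues absent from substitution matrix: ",
                 paste(bad, collapse = ", ")),
          class = "tcrsplit_alphabet_error")
  }
  invisible(TRUE)
}

#' Levenshtein edit distance between sequences
#'
#' Unit-cost edit distance (insertions, deletions and substitutions each
#' cost 1), computed pairwise between `a[i]` and `b[i]`.
#'
#' @param a,b Character vectors of non-empty sequences (recycled).
#' @return Integer vector of distances.
#' @export
levenshtein_distance <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    abort("sequences must be non-empty", class = "tcrsplit_precondition_error")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[[i]], b[[i]])[1L, 1L]),
         integer(1))
}

#' Global alignment score
#'
#' Optimal Needleman-Wunsch global alignment score under a substitution
#' matrix and affine gap penalties (see [alignment_params()] for the gap
#' convention), computed by the package's Gotoh dynamic-programming
#' kernel. Vectorised over `a` against a single `b`.
#'
#' @param a Character vector of sequences.
#' @param b A single sequence.
#' @param params [alignment_params()].
#' @return Numeric vector of scores, one per element of `a`.
#' @export
global_alignment_score <- function(a, b, params = alignment_params()) {
  mat <- substitution_matrix(params$matrix)
  bi <- seq_to_idx(b, mat)
  vapply(a, function(x)
    .cpp_nw_score(seq_to_idx(x, mat), bi, mat, params$gap_open,
                  params$gap_extend),
    numeric(1), USE.NAMES = FALSE)
}

#' BLOSUM alignment distance between sequences
#'
#' Converts global-alignment similarity `S` into a pseudo-distance
#' `d(a, b) = S(a, a) + S(b, b) - 2 S(a, b)`, clamped at 0, so that the
#' self-distance is exactly 0 and the distance is symmetric. Higher values
#' mean lower evolutionary similarity under the chosen BLOSUM matrix.
#'
#' @param a,b Single sequences.
#' @param params [alignment_params()].
#' @return Non-negative numeric distance.
#' @export
blosum_distance <- function(a, b, params = alignment_params()) {
  saa <- global_alignment_score(a, a, params)
  sbb <- global_alignment_score(b, b, params)
  sab <- global_alignment_score(a, b, params)
  max(0, saa + sbb - 2 * sab)
}
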