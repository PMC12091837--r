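#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body superposition of point set `p` onto `q` via the
#' Kabsch algorithm (SVD of the covariance matrix, with the reflection
#' branch corrected so that only proper rotations are returned).
#'
#' @param p,q Numeric n x 3 matrices of equal length, n >= 3, not all
#'   collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector) such that `q ~ p %*% t(rotation) + translation`, and `rmsd`,
#'   the root-mean-square deviation after superposition, in Angstrom.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 3L || ncol(q) != 3L) {
    abort("`p` and `q` must be n x 3 matrices of equal length",
          class = "tcrsplit_precondition_error")
  }
  if (nrow(p) < 3L) {
    abort("at least 3 points are required",
          class = "tcrsplit_precondition_error")
  }
  pc <- colMeans(p); qc <- colMeans(q)
  P <- sweep(p, 2L, pc); Q <- sweep(q, 2L, qc)
  sp <- svd(P)$d
  if (sp[2L] < 1e-8 * max(1, sp[1L])) {
    abort("points are (nearly) collinear; rotation is not determined",
          class = "tcrsplit_degenerate_error")
  }
  H <- crossprod(P, Q)               # 3 x 3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Q)^2)))
  list(rotation = R,
       translation = as.numeric(qc - R %*% pc),
       rmsd = rmsd)
}

#' Pair C-alpha atoms of two peptides by sequence alignment
#'
#' Residue correspondence for the RMSD metric: the two sequences are
#' globally aligned (same parameters as the BLOSUM distance) and the match
#' (non-gap) columns give the paired residue indices.
#'
#' @param x,y [peptide_structure()] objects.
#' @param params [alignment_params()].
#' @return Two-column integer matrix of 1-based residue indices (`i` in
#'   `x`, `j` in `y`), strictly increasing in both columns.
#' @export
pair_ca_atoms <- function(x, y, params = alignment_params()) {
  stopifnot(inherits(x, "peptide_structure"), inherits(y, "peptide_structure"))
  mat <- substitution_matrix(params$matrix)
  pairs <- .cpp_nw_pairs(seq_to_idx(x$sequence, mat),
                         seq_to_idx(y$sequence, mat),
                         mat, params$gap_open, params$gap_extend)
  if (nrow(pairs) == 0L) {
    abort("alignment has no match columns; structures cannot be paired",
          class = "tcrsplit_no_overlap_error")
  }
  pairs
}

## Alignment-based pairing with a degenerate-case fallback: when the
## optimal global alignment is (almost) completely gapped, pair by the
## best ungapped offset (maximum substitution score over an overlap of
## >= 3, first optimum on ties) so the RMSD stays defined.
ca_pairs <- function(a, b, params,
                     mat = substitution_matrix(params$matrix)) {
  pairs <- .cpp_nw_pairs(seq_to_idx(a, mat), seq_to_idx(b, mat), mat,
                         params$gap_open, params$gap_extend)
  if (nrow(pairs) >= 3L) return(pairs)
  ungapped_fallback_pairs(a, b, mat)
}

ungapped_fallback_pairs <- function(a, b, mat) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  m <- length(ac); n <- length(bc)
  best <- NULL; best_score <- -Inf
  for (shift in seq(-(n - 3L), m - 3L)) {
    i <- seq(max(1L, shift + 1L), min(m, n + shift))
    j <- i - shift
    if (length(i) < 3L) next
    sc <- sum(mat[cbind(ac[i], bc[j])])
    if (sc > best_score) {
      best_score <- sc
      best <- cbind(i = i, j = j)
    }
  }
  best
}

#' C-alpha RMSD between two peptide structures
#'
#' Pairs residues by global sequence alignment ([pair_ca_atoms()]),
#' superposes the paired C-alpha sets ([kabsch_superpose()]), then runs up
#' to `refine_cycles` outlier-rejection rounds in which pairs deviating by
#' more than `outlier_cutoff` Angstrom are removed and the superposition is
#' repeated -- mirroring the behaviour of PyMOL's `align`. Refinement stops
#' early when no pair is rejected or fewer than 3 pairs would remain.
#'
#' When the optimal global alignment is completely gapped (possible for
#' very dissimilar sequences), residues are paired by the best ungapped
#' offset instead, so the distance stays defined for every pair.
#'
#' @param x,y [peptide_structure()] objects.
#' @param params [alignment_params()] used for the residue pairing.
#' @param refine_cycles Maximum number of rejection rounds (0 = plain
#'   superposition of all matched pairs).
#' @param outlier_cutoff Rejection threshold in Angstrom.
#' @return The final RMSD in Angstrom (non-negative scalar).
#' @export
ca_rmsd <- function(x, y, params = alignment_params(), refine_cycles = 5L,
                    outlier_cutoff = 2.0) {
  stopifnot(inherits(x, "peptide_structure"), inherits(y, "peptide_structure"))
  pairs <- ca_pairs(x$sequence, y$sequence, params)
  if (is.null(pairs) || nrow(pairs) < 3L) {
    abort("fewer than 3 paired C-alpha atoms",
          class = "tcrsplit_degenerate_error")
  }
  .cpp_rmsd_refine(x$ca, y$ca, pairs, as.integer(refine_cycles),
                   outlier_cutoff)
}
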