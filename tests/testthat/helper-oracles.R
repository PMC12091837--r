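## Independent oracles used to verify the implementation on small inputs.
## These are written from the definitions, not from the package code paths.

## Edit distance by memoised recursion on the defining recurrence.
oracle_edit_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  memo <- matrix(NA_integer_, length(ac) + 1L, length(bc) + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j else if (j == 0L) i else {
      min(rec(i - 1L, j) + 1L,
          rec(i, j - 1L) + 1L,
          rec(i - 1L, j - 1L) + (ac[i] != bc[j]))
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(length(ac), length(bc))
}

## Score one explicit alignment (two gapped strings) under affine gaps:
## a gap of length L costs -(gap_open + (L - 1) * gap_extend).
score_alignment <- function(a_aln, b_aln, mat, gap_open, gap_extend) {
  score <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(a_aln)) {
    a <- a_aln[k]; b <- b_aln[k]
    if (a == "-") {
      score <- score + if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (b == "-") {
      score <- score + if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      score <- score + mat[a, b]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  score
}

## Brute-force optimal global alignment score: enumerate every alignment
## (sequence of match/insert/delete moves) and take the best score.
oracle_alignment_score <- function(a, b, mat, gap_open = -10,
                                   gap_extend = -1) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  best <- -Inf
  rec <- function(i, j, acol, bcol) {
    if (i > length(ac) && j > length(bc)) {
      s <- score_alignment(acol, bcol, mat, gap_open, gap_extend)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1L, j + 1L, c(acol, ac[i]), c(bcol, bc[j]))
    }
    if (i <= length(ac)) rec(i + 1L, j, c(acol, ac[i]), c(bcol, "-"))
    if (j <= length(bc)) rec(i, j + 1L, c(acol, "-"), c(bcol, bc[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

## All optimal-alignment match-column index pairings (for tiny cases).
oracle_alignments <- function(a, b, mat, gap_open = -10, gap_extend = -1) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  out <- list()
  rec <- function(i, j, acol, bcol) {
    if (i > length(ac) && j > length(bc)) {
      out[[length(out) + 1L]] <<- list(
        a = acol, b = bcol,
        score = score_alignment(acol, bcol, mat, gap_open, gap_extend))
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1L, j + 1L, c(acol, ac[i]), c(bcol, bc[j]))
    }
    if (i <= length(ac)) rec(i + 1L, j, c(acol, ac[i]), c(bcol, "-"))
    if (j <= length(bc)) rec(i, j + 1L, c(acol, "-"), c(bcol, bc[j]))
  }
  rec(1L, 1L, character(0), character(0))
  out
}

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t),  cos(t), 0,
                             0, 0, 1), 3L, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t),
                             0, 1, 0,
                             -sin(t), 0, cos(t)), 3L, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

rmsd_at_rotation <- function(P, Q, R) {
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

## Minimum RMSD over rotations by coarse Euler-angle grid search followed
## by Nelder-Mead refinement (translation handled by centering).
oracle_min_rmsd <- function(p, q, grid_step = 15) {
  P <- sweep(p, 2L, colMeans(p))
  Q <- sweep(q, 2L, colMeans(q))
  steps_full <- seq(0, 2 * pi, by = grid_step * pi / 180)
  steps_half <- seq(0, pi, by = grid_step * pi / 180)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in steps_full) for (b in steps_half) for (c in steps_full) {
    v <- rmsd_at_rotation(P, Q, euler_rotation(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, function(ang)
    rmsd_at_rotation(P, Q, euler_rotation(ang[1], ang[2], ang[3])),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

## Random proper rotation via QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

## AUROC by explicit pair counting (ties count half).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

random_peptide <- function(len) {
  paste(sample(tcrsplit:::AA20, len, replace = TRUE), collapse = "")
}
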