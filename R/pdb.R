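#' Construct a peptide structure
#'
#' A peptide structure is the ordered C-alpha trace of a single short chain:
#' one 3D point per residue, in Angstrom, together with the one-letter
#' sequence. Only the C-alpha atoms are kept: they summarise the backbone
#' without penalising side-chain placement artifacts common in predicted
#' structures.
#'
#' @param sequence One-letter amino-acid string.
#' @param ca Numeric matrix with one row per residue and columns x, y, z (A).
#' @param source_id Free-text provenance tag (e.g. the source file).
#' @return An object of class `peptide_structure`.
#' @export
peptide_structure <- function(sequence, ca, source_id = "") {
  sequence <- toupper(as.character(sequence)[[1L]])
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  if (nchar(sequence) == 0L) {
    abort("empty sequence", class = "tcrsplit_precondition_error")
  }
  if (!grepl(AA20_REGEX, sequence)) {
    abort("sequence contains non-standard residues",
          class = "tcrsplit_alphabet_error")
  }
  if (ncol(ca) != 3L || nrow(ca) != nchar(sequence)) {
    abort("`ca` must be an n x 3 matrix with one row per residue",
          class = "tcrsplit_precondition_error")
  }
  if (nrow(ca) > 1L) {
    step <- sqrt(rowSums((ca[-1L, , drop = FALSE] -
                          ca[-nrow(ca), , drop = FALSE])^2))
    if (any(step < 1e-9)) {
      abort("consecutive C-alpha positions must differ",
            class = "tcrsplit_precondition_error")
    }
  }
  dimnames(ca) <- list(NULL, c("x", "y", "z"))
  structure(list(sequence = sequence, ca = ca,
                 source_id = as.character(source_id)),
            class = "peptide_structure")
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat("<peptide_structure> ", x$sequence, " (", nrow(x$ca), " CA)\n", sep = "")
  invisible(x)
}

#' @export
length.peptide_structure <- function(x) nrow(x$ca)

#' Read a peptide C-alpha trace from a PDB file
#'
#' Reads the first model and first chain of a PDB file and extracts one
#' C-alpha per residue in file order. Alternate locations are resolved by
#' highest occupancy (ties broken by file order); residues without a
#' C-alpha atom, and residues with a non-standard name, are skipped and
#' counted in the `skip_report` attribute.
#'
#' @param path Path to a PDB file.
#' @return A [peptide_structure()] with a `skip_report` attribute (tibble
#'   with columns `reason`, `n`).
#' @export
read_peptide_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      abort(paste0("cannot parse PDB file: ", path),
            class = "tcrsplit_format_error", parent = e)
    })
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    abort("no ATOM records", class = "tcrsplit_empty_structure_error")
  }
  chain <- atoms$chain[[1L]]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]

  ## residues in file order (resno + insertion code)
  res_key <- paste(atoms$resno, ifelse(is.na(atoms$insert), "", atoms$insert))
  res_order <- unique(res_key)

  n_no_ca <- 0L
  n_nonstd <- 0L
  seq_ch <- character(0)
  coords <- list()
  for (rk in res_order) {
    ra <- atoms[res_key == rk, , drop = FALSE]
    ca <- ra[ra$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      n_no_ca <- n_no_ca + 1L
      next
    }
    ca <- ca[order(-ca$o)[1L], , drop = FALSE]  # highest occupancy, first on tie
    one <- suppressWarnings(bio3d::aa321(ca$resid))
    if (is.na(one) || one == "X" || !one %in% AA20) {
      n_nonstd <- n_nonstd + 1L
      next
    }
    seq_ch <- c(seq_ch, one)
    coords[[length(coords) + 1L]] <- c(ca$x, ca$y, ca$z)
  }
  if (length(coords) == 0L) {
    abort(paste0("no usable C-alpha atoms in ", path),
          class = "tcrsplit_empty_structure_error")
  }
  ps <- peptide_structure(paste(seq_ch, collapse = ""),
                          do.call(rbind, coords),
                          source_id = basename(path))
  attr(ps, "skip_report") <- tibble(
    reason = c("missing_ca", "nonstandard_residue"),
    n = c(n_no_ca, n_nonstd))
  ps
}

#' Write a peptide structure to a PDB file
#'
#' Writes one ATOM record per residue (the C-alpha), chain A, in standard
#' fixed-width PDB format. Coordinates survive a write/read round trip to
#' the 1e-3 A precision of the format.
#'
#' @param ps A [peptide_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_pdb <- function(ps, path) {
  stopifnot(inherits(ps, "peptide_structure"))
  n <- nrow(ps$ca)
  resid3 <- bio3d::aa123(strsplit(ps$sequence, "")[[1L]])
  tryCatch(
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(ps$ca)),
                     resno = seq_len(n),
                     resid = resid3,
                     eleno = seq_len(n),
                     elety = rep("CA", n),
                     chain = rep("A", n),
                     o = rep(1, n),
                     b = rep(0, n)),
    error = function(e) {
      abort(paste0("cannot write PDB file: ", path),
            class = "tcrsplit_io_error", parent = e)
    })
  invisible(path)
}

#' Read one structure per peptide from a directory
#'
#' Expects `<dir>/<peptide>.pdb` for every requested peptide; errors if a
#' structure is missing or if a peptide has several candidate files.
#'
#' @param peptides Character vector of peptide sequences.
#' @param dir Directory containing one PDB file per peptide.
#' @return Named list of [peptide_structure()], in `peptides` order.
#' @export
read_structure_dir <- function(peptides, dir) {
  paths <- file.path(dir, paste0(peptides, ".pdb"))
  missing <- peptides[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("missing structure files for: ",
                 paste(utils::head(missing, 5L), collapse = ", ")),
          class = "tcrsplit_missing_structure_error")
  }
  setNames(lapply(paths, read_peptide_pdb), peptides)
}
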