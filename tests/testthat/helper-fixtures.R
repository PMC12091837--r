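## Small in-code fixtures shared across test files.

tiny_interactions <- function() {
  tibble::tibble(
    peptide = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "ELAGIGILTV"),
    cdr3b = c("CASSIRSSYEQYF", "CASSLAPGATNEKLFF", "CASSIRSSYEQYF",
              "CASSQDRDTQYF"),
    label = c(1L, 1L, 1L, 1L))
}

## Write a PDB text fixture directly (to exercise parser edge cases the
## package writer never produces: altlocs, multi-model, missing CA).
write_pdb_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          altloc = " ", occ = 1, chain = "A") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z, occ, 0)
}

## Simple non-collinear CA trace with valid consecutive spacing.
ideal_ca <- function(n) {
  cbind(x = 3.6 * seq_len(n), y = 1.2 * (seq_len(n) %% 2),
        z = 0.3 * seq_len(n))
}

helix_structure <- function(seq = "ACDEFGHIK", jitter = 0, seed = 1) {
  spec <- fixture_spec(n_peptides = 2, jitter_sd = jitter, seed = seed)
  ps <- generate_structures(seq, spec)[[1L]]
  ps
}
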