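#' Specification of a synthetic fixture
#'
#' Describes a synthetic TCR-peptide dataset with the statistical shape the
#' splitting method assumes: random peptides of length 8-11 over the
#' 20-letter alphabet, per-peptide record counts that are heavily
#' right-skewed (most peptides have fewer than 10 records, a few have
#' many), paired CDR3-beta strings, binary labels, and per-peptide C-alpha
#' backbones written as PDB.
#'
#' @param n_peptides Number of unique peptides (>= 2).
#' @param length_range Inclusive peptide length range, within 5-20.
#' @param count_distribution `"skewed_powerlaw"` (default; Pareto-tailed
#'   counts with median ~2, truncated at 500) or `"uniform"` (all counts
#'   equal `uniform_count`).
#' @param uniform_count Per-peptide count under `"uniform"`.
#' @param n_cdr3b Size of the CDR3-beta pool (default
#'   `max(10 * n_peptides, 600)`, so the pool always exceeds the truncated
#'   maximum per-peptide count).
#' @param label_model `"random"` (fair coin) or `"peptide_keyed"`: each
#'   peptide gets a latent binding propensity in \[0.1, 0.9\] and labels are
#'   Bernoulli draws from it, so a predictor that memorises peptides gains
#'   signal -- the mechanism Random vs Hard Split comparisons expose.
#' @param structure_model `"helix_jitter"` (ideal alpha-helix backbone) or
#'   `"extended_jitter"` (extended zigzag), plus isotropic Gaussian noise.
#' @param jitter_sd Coordinate noise standard deviation in Angstrom
#'   (default 0.3, small enough that jittered consecutive C-alpha spacings
#'   stay inside the physical 2.0-4.5 A window).
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_peptides, length_range = c(8L, 11L),
                         count_distribution = c("skewed_powerlaw", "uniform"),
                         uniform_count = 10L,
                         n_cdr3b = max(10L * n_peptides, 600L),
                         label_model = c("random", "peptide_keyed"),
                         structure_model = c("helix_jitter",
                                             "extended_jitter"),
                         jitter_sd = 0.3, seed = 1L) {
  count_distribution <- arg_match(count_distribution)
  label_model <- arg_match(label_model)
  structure_model <- arg_match(structure_model)
  if (n_peptides < 2L) {
    abort("need n_peptides >= 2", class = "tcrsplit_precondition_error")
  }
  length_range <- as.integer(length_range)
  if (length_range[[1L]] < 5L || length_range[[2L]] > 20L ||
      length_range[[1L]] > length_range[[2L]]) {
    abort("`length_range` must lie within [5, 20]",
          class = "tcrsplit_precondition_error")
  }
  if (jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0", class = "tcrsplit_precondition_error")
  }
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = length_range,
                 count_distribution = count_distribution,
                 uniform_count = as.integer(uniform_count),
                 n_cdr3b = as.integer(n_cdr3b),
                 label_model = label_model,
                 structure_model = structure_model,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

random_aa_strings <- function(n, len_min, len_max, prefix = "",
                              suffix = "") {
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 100L) {
    tries <- tries + 1L
    lens <- sample(seq(len_min, len_max), n, replace = TRUE)
    fresh <- vapply(lens, function(l)
      paste0(prefix, paste(sample(AA20, l, replace = TRUE), collapse = ""),
             suffix), character(1))
    out <- unique(c(out, fresh))
  }
  if (length(out) < n) {
    abort("cannot generate enough unique sequences for this alphabet/length",
          class = "tcrsplit_infeasible_error")
  }
  out[seq_len(n)]
}

#' Generate unique peptides with record counts
#'
#' Under the skewed distribution, counts are `ceiling(1/U)` draws (a
#' discrete Pareto with tail index 1), truncated at 500: the sample median
#' is ~2 while the mean is much larger, matching the heavy right skew seen
#' in real interaction databases.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble with columns `peptide` and `count`.
#' @export
generate_peptides <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    peps <- random_aa_strings(spec$n_peptides, spec$length_range[[1L]],
                              spec$length_range[[2L]])
    counts <- if (spec$count_distribution == "uniform") {
      rep(spec$uniform_count, spec$n_peptides)
    } else {
      pmin(500L, as.integer(ceiling(1 / runif(spec$n_peptides))))
    }
    tibble(peptide = peps, count = counts)
  })
}

ideal_backbone <- function(n, model) {
  i <- seq_len(n) - 1L
  if (model == "helix_jitter") {
    ## alpha-helix: 100 deg turn and 1.5 A rise per residue, 2.3 A radius
    ang <- i * 100 * pi / 180
    cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
  } else {
    ## extended zigzag: ~3.8 A between consecutive C-alpha
    cbind(x = 3.3 * i, y = 1.9 * (i %% 2), z = rep(0, n))
  }
}

#' Generate synthetic peptide structures
#'
#' One C-alpha trace per peptide: an ideal backbone curve (alpha-helix or
#' extended) with isotropic Gaussian jitter. Geometry depends only on the
#' peptide length, and the jitter is independent of the sequence, so
#' structure distances carry no sequence signal by construction. Draws are
#' retried (up to 20 times per peptide) until consecutive C-alpha spacings
#' stay within the physical 2.0-4.5 A window.
#'
#' @param peptides Character vector of peptide sequences.
#' @param spec A [fixture_spec()].
#' @return Named list of [peptide_structure()].
#' @export
generate_structures <- function(peptides, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (length(peptides) == 0L) {
    abort("`peptides` must be non-empty",
          class = "tcrsplit_precondition_error")
  }
  withr::with_seed(spec$seed + 1L, {
    out <- lapply(peptides, function(p) {
      n <- nchar(p)
      base <- ideal_backbone(n, spec$structure_model)
      for (try in seq_len(20L)) {
        ca <- base + matrix(rnorm(3L * n, sd = spec$jitter_sd), ncol = 3L)
        step <- sqrt(rowSums((ca[-1L, , drop = FALSE] -
                              ca[-n, , drop = FALSE])^2))
        if (all(step > 2.0 & step < 4.5)) {
          return(peptide_structure(p, ca, source_id = "synthetic"))
        }
      }
      abort("jitter too large to satisfy the C-alpha spacing invariant",
            class = "tcrsplit_infeasible_error")
    })
    setNames(out, peptides)
  })
}

#' Generate a synthetic interaction table
#'
#' For each peptide, draws `count` CDR3-beta partners (without replacement)
#' from a shared pool of CDR3-like strings (`C...F` flanks), and assigns
#' binary labels according to the label model of the spec. Under
#' `"peptide_keyed"` labels, the latent per-peptide propensities are
#' attached as the `propensity` attribute.
#'
#' @param peptides Tibble from [generate_peptides()] (columns `peptide`,
#'   `count`).
#' @param spec A [fixture_spec()].
#' @return Canonical interaction tibble.
#' @export
generate_interactions <- function(peptides, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (max(peptides$count) > spec$n_cdr3b) {
    abort("`n_cdr3b` is smaller than the largest per-peptide count",
          class = "tcrsplit_infeasible_error")
  }
  withr::with_seed(spec$seed + 2L, {
    pool <- random_aa_strings(spec$n_cdr3b, 8L, 14L, prefix = "C",
                              suffix = "F")
    prop <- if (spec$label_model == "peptide_keyed") {
      setNames(runif(nrow(peptides), 0.1, 0.9), peptides$peptide)
    }
    rows <- lapply(seq_len(nrow(peptides)), function(i) {
      p <- peptides$peptide[[i]]
      k <- peptides$count[[i]]
      cdrs <- sample(pool, k, replace = FALSE)
      lab <- if (spec$label_model == "random") {
        sample(0:1, k, replace = TRUE)
      } else {
        as.integer(runif(k) < prop[[p]])
      }
      tibble(peptide = p, cdr3b = cdrs, cdr3a = NA_character_,
             mhc_allele = NA_character_, label = lab, source = "observed")
    })
    out <- bind_rows(rows)
    if (!is.null(prop)) {
      attr(out, "propensity") <- tibble(peptide = names(prop),
                                        propensity = unname(prop))
    }
    out
  })
}

#' Generate and write a complete fixture
#'
#' Convenience wrapper: peptides + counts, interaction table, one PDB per
#' peptide, and a manifest JSON, written into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `interactions` (path), `structure_dir`, `manifest`.
#' @export
generate_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peps <- generate_peptides(spec)
  ds <- generate_interactions(peps, spec)
  structs <- generate_structures(peps$peptide, spec)
  tab_path <- file.path(dir, "interactions.tsv")
  write_interaction_table(ds, tab_path)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  for (p in names(structs)) {
    write_peptide_pdb(structs[[p]], file.path(sdir, paste0(p, ".pdb")))
  }
  manifest <- c(unclass(spec),
                list(package = "tcrsplit",
                     version = as.character(packageVersion("tcrsplit"))))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  list(interactions = tab_path, structure_dir = sdir, manifest = mpath)
}
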