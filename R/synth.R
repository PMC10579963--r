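#' Synthetic motif-bearing peptide corpus
#'
#' Generates a structured training-style corpus: lengths uniform in
#' `length_range`, an optional motif implanted at a seeded position in every
#' sequence (giving a sequence model learnable structure), and a residue
#' composition bias applied to non-motif positions. Reproducible from
#' `seed`.
#'
#' @param n Number of peptides.
#' @param length_range Inclusive `(min, max)` residue counts (default
#'   `c(9, 15)`, the training-corpus range).
#' @param motif Optional motif string implanted in every sequence; must fit
#'   within the minimum length.
#' @param composition_bias Optional named weights over residues for
#'   non-motif positions (need not be normalized).
#' @param seed Integer seed.
#' @param provenance Provenance tag (default `"training"`).
#' @return A corpus tibble.
#' @export
synth_corpus <- function(n, length_range = c(9L, 15L), motif = NULL,
                         composition_bias = NULL, seed = 1L,
                         provenance = "training") {
  if (n == 0L) return(corpus(character(), character(), provenance))
  if (length_range[1] > length_range[2] || length_range[1] < 1L) {
    abort("invalid length_range", class = "pepgen_config_error")
  }
  if (!is.null(motif)) {
    assert_canonical(motif, "motif")
    if (nchar(motif) > length_range[1]) {
      abort("motif longer than the minimum sequence length",
            class = "pepgen_config_error")
    }
  }
  probs <- rep(1 / 20, 20)
  if (!is.null(composition_bias)) {
    w <- rep(0, 20)
    names(w) <- AA20
    w[names(composition_bias)] <- composition_bias
    if (sum(w) <= 0) abort("composition_bias has no mass",
                           class = "pepgen_config_error")
    probs <- w / sum(w)
  }
  with_seed_(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      res <- sample(AA20, L, replace = TRUE, prob = probs)
      if (!is.null(motif)) {
        m <- nchar(motif)
        at <- sample.int(L - m + 1L, 1L)
        res[at:(at + m - 1L)] <- split_seq(motif)
      }
      paste(res, collapse = "")
    }, character(1))
    corpus(sprintf("syn_%05d", seq_len(n)), seqs, provenance)
  })
}

#' Synthetic contact records with a planted variance split
#'
#' Generates integer per-frame contact series such that exactly
#' `n_low_variance` of the `n_total` series have sample variance at most
#' `cutoff` — verified by direct recomputation at generation time and
#' resampled until satisfied — plus binding energies drawn on both sides of
#' the 17 kcal/mol magnitude threshold (MMPBSA sign convention, negative =
#' favorable).
#'
#' @param n_total Number of records (default 127, the screening pool size).
#' @param n_low_variance How many series must pass the variance cut
#'   (default 57).
#' @param cutoff Variance cut-off (default 3).
#' @param n_frames Frames per series (default 50).
#' @param seed Integer seed.
#' @return Tibble with columns `peptide_id`, `series` (list-column of
#'   integer counts), `contact_variance`, `binding_energy`.
#' @export
synth_contact_records <- function(n_total = 127L, n_low_variance = 57L,
                                  cutoff = 3.0, n_frames = 50L, seed = 1L) {
  if (cutoff < 0) abort("cutoff must be non-negative",
                        class = "pepgen_config_error")
  if (n_low_variance > n_total) {
    abort("n_low_variance cannot exceed n_total", class = "pepgen_config_error")
  }
  with_seed_(seed, {
    draw_series <- function(low) {
      repeat {
        base <- sample(3:12, 1L)
        s <- if (low) {
          base + sample(c(-1L, 0L, 1L), n_frames, replace = TRUE)
        } else {
          base + sample(-6:6, n_frames, replace = TRUE)
        }
        s <- pmax(s, 0L)
        v <- var(s)                       # generation-time verification
        if ((low && v <= cutoff) || (!low && v > cutoff)) return(s)
      }
    }
    low_flags <- rep(c(TRUE, FALSE), c(n_low_variance, n_total - n_low_variance))
    low_flags <- sample(low_flags)
    series <- lapply(low_flags, draw_series)
    energies <- -runif(n_total, 8, 26)    # straddles the 17 kcal/mol threshold
    tibble(
      peptide_id = sprintf("pep_%03d", seq_len(n_total)),
      series = series,
      contact_variance = map_dbl(series, var),
      binding_energy = energies
    )
  })
}

#' Synthetic two-chain trajectory with a scheduled contact count
#'
#' Builds a toy peptide-receptor system of single-carbon residues on two
#' chains in which the number of residue pairs within 4.0 A in frame `t`
#' equals `contact_schedule[t]`: scheduled pairs sit 3.5 A apart, all other
#' pairs at least 8 A. Round-trips through [write_trajectory()] /
#' [read_trajectory()].
#'
#' @param contact_schedule Integer vector of per-frame target contact
#'   counts.
#' @param n_residues Residues per chain (default 6); the schedule may not
#'   exceed `n_residues` (contacts are formed pairwise down the chains).
#' @param seed Unused placeholder for interface symmetry (the construction
#'   is deterministic).
#' @return A `pep_trajectory` with chains `"A"` (peptide) and `"B"`
#'   (receptor).
#' @export
synth_trajectory <- function(contact_schedule, n_residues = 6L, seed = 1L) {
  if (length(contact_schedule) < 1L) {
    abort("need at least one frame", class = "pepgen_config_error")
  }
  if (any(contact_schedule > n_residues) || any(contact_schedule < 0L)) {
    abort(sprintf("schedule values must lie in [0, %d]", n_residues),
          class = "pepgen_config_error")
  }
  # chain A residue i at x = 20*i; chain B residue i directly "below" it:
  # at dy = 3.5 when residue i is scheduled to touch, else dy = 8.
  atoms <- tibble(
    name = "CA",
    resname = rep(c("ALA", "GLY"), each = n_residues),
    chain = rep(c("A", "B"), each = n_residues),
    resid = rep(seq_len(n_residues), 2L),
    element = "C"
  )
  n_frames <- length(contact_schedule)
  coords <- array(0, dim = c(n_frames, 2L * n_residues, 3L))
  for (f in seq_len(n_frames)) {
    k <- contact_schedule[f]
    for (i in seq_len(n_residues)) {
      coords[f, i, ] <- c(20 * i, 0, 0)
      dy <- if (i <= k) 3.5 else 8.0
      coords[f, n_residues + i, ] <- c(20 * i, dy, 0)
    }
  }
  structure(list(atoms = atoms, coords = coords), class = "pep_trajectory")
}

#' Synthetic CD basis set
#'
#' Smooth, distinguishable toy basis curves on a 190-250 nm grid: a
#' helix-like class with double negative bands near 208 and 222 nm, a
#' sheet-like class with a single negative band near 216 nm, and a coil-like
#' class with a negative band near 198 nm. Small seeded perturbations make
#' distinct seeds give distinct bases.
#'
#' @param n_classes 1 to 3 classes (helix, sheet, coil in that order).
#' @param grid Wavelength grid in nm (default 190-250, step 1).
#' @param seed Integer seed.
#' @return A `cd_basis`.
#' @export
synth_basis <- function(n_classes = 3L, grid = seq(190, 250), seed = 1L) {
  if (n_classes < 1L || n_classes > 3L) {
    abort("n_classes must be 1, 2 or 3", class = "pepgen_config_error")
  }
  gauss <- function(center, width, depth) depth * exp(-((grid - center)^2) /
                                                        (2 * width^2))
  with_seed_(seed, {
    jitter_amp <- function() runif(1, 0.95, 1.05)
    helix <- gauss(208, 9, -11000) * jitter_amp() +
      gauss(222, 10, -12000) * jitter_amp() + gauss(193, 7, 25000)
    sheet <- gauss(216, 11, -9000) * jitter_amp() + gauss(196, 8, 14000)
    coil <- gauss(198, 9, -15000) * jitter_amp() + gauss(222, 14, 2500)
    basis <- cbind(helix, sheet, coil)[, seq_len(n_classes), drop = FALSE]
    new_cd_basis(grid, c("helix", "sheet", "coil")[seq_len(n_classes)], basis)
  })
}
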