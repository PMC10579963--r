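#' Uniform-random peptide baseline
#'
#' Residues drawn uniformly from the 20 canonical amino acids; lengths drawn
#' from `length_sampler`. Fully reproducible from `seed`.
#'
#' @param n Number of peptides.
#' @param length_sampler Function of one argument `n` returning `n` integer
#'   lengths; defaults to uniform over 9-15 residues. Pass
#'   [empirical_length_sampler()] to match a training corpus.
#' @param seed Integer seed.
#' @return A corpus tibble with `provenance = "random"`.
#' @export
random_baseline <- function(n, length_sampler = NULL, seed = 1L) {
  if (is.null(length_sampler)) {
    length_sampler <- function(k) sample(9:15, k, replace = TRUE)
  }
  if (n == 0L) return(corpus(character(), character(), "random"))
  with_seed_(seed, {
    lens <- length_sampler(n)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1))
    corpus(sprintf("rand_%05d", seq_len(n)), seqs, "random")
  })
}

#' Length sampler matching a corpus' empirical length distribution
#'
#' @param x A corpus tibble.
#' @return A function usable as `length_sampler` in the baseline generators.
#' @export
empirical_length_sampler <- function(x) {
  lens <- nchar(validate_corpus(x, allow_empty = FALSE)$sequence)
  function(k) sample(lens, k, replace = TRUE)
}

# residue pools for the amphipathic helical baseline
HELICAL_HYDROPHOBIC_POOL <- c("A", "F", "I", "L", "M", "V", "W")
HELICAL_POLAR_POOL <- c("D", "E", "H", "K", "N", "Q", "R", "S", "T")

#' Amphipathic helical peptide baseline
#'
#' Residues are placed on an ideal helical wheel at 100 degrees per residue:
#' positions whose angle falls inside a 180-degree hydrophobic arc draw from
#' the hydrophobic pool, the rest from the polar/charged pool. By
#' construction every output has a positive hydrophobic moment.
#'
#' @inheritParams random_baseline
#' @param hydrophobic_pool,polar_pool Residue sets for the two faces.
#' @return A corpus tibble with `provenance = "helical"`.
#' @export
helical_baseline <- function(n, length_sampler = NULL, seed = 1L,
                             hydrophobic_pool = HELICAL_HYDROPHOBIC_POOL,
                             polar_pool = HELICAL_POLAR_POOL) {
  if (is.null(length_sampler)) {
    length_sampler <- function(k) sample(9:15, k, replace = TRUE)
  }
  if (n == 0L) return(corpus(character(), character(), "helical"))
  with_seed_(seed, {
    lens <- length_sampler(n)
    seqs <- vapply(lens, function(L) {
      ang <- (seq_len(L) * 100) %% 360
      hydro <- ang < 180
      res <- character(L)
      res[hydro] <- sample(hydrophobic_pool, sum(hydro), replace = TRUE)
      res[!hydro] <- sample(polar_pool, sum(!hydro), replace = TRUE)
      paste(res, collapse = "")
    }, character(1))
    corpus(sprintf("hel_%05d", seq_len(n)), seqs, "helical")
  })
}
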