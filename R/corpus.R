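#' Build a peptide corpus tibble
#'
#' A corpus is an ordinary tibble with columns `id`, `sequence` and
#' `provenance`; every user-facing function in the package accepts and
#' returns this shape so corpora chain naturally through pipes.
#'
#' @param id Character vector of unique peptide identifiers.
#' @param sequence Character vector of sequences over the 20 canonical
#'   one-letter amino-acid codes.
#' @param provenance One of `"training"`, `"generated"`, `"random"`,
#'   `"helical"`, `"external"`; recycled to the corpus length.
#' @return A tibble with columns `id`, `sequence`, `provenance`.
#' @export
#' @examples
#' corpus(c("p1", "p2"), c("ACDEFGHIK", "KLMNPQRST"))
corpus <- function(id, sequence, provenance = "external") {
  provenance <- match.arg(provenance,
                          c("training", "generated", "random", "helical",
                            "external"))
  sequence <- toupper(sequence)
  out <- tibble(id = as.character(id), sequence = sequence,
                provenance = provenance)
  validate_corpus(out)
}

validate_corpus <- function(x, allow_empty = TRUE) {
  need <- c("id", "sequence", "provenance")
  if (!all(need %in% names(x))) {
    abort(sprintf("a corpus needs columns %s",
                  paste(sprintf("'%s'", need), collapse = ", ")),
          class = "pepgen_validation_error")
  }
  if (nrow(x) == 0L) {
    if (!allow_empty) abort("corpus is empty", class = "pepgen_validation_error")
    return(as_tibble(x))
  }
  if (anyDuplicated(x$id)) {
    abort(sprintf("duplicate peptide id(s): %s",
                  paste(unique(x$id[duplicated(x$id)]), collapse = ", ")),
          class = "pepgen_validation_error")
  }
  purrr::walk2(x$sequence, x$id, assert_canonical)
  as_tibble(x)
}

#' Read a peptide corpus from a FASTA file
#'
#' Headers become peptide ids (up to the first whitespace), sequences are
#' upper-cased, and record order is preserved. Non-canonical residues raise
#' a validation error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @param provenance Provenance tag assigned to every record.
#' @return A corpus tibble (see [corpus()]).
#' @export
read_fasta <- function(path, provenance = "external") {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file '%s' does not exist", path),
          class = "pepgen_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
            class = "pepgen_parse_error")
    }
  )
  if (length(set) == 0L) {
    warn(sprintf("FASTA file '%s' contains no records", path))
    return(corpus(character(), character(), provenance))
  }
  ids <- sub("\\s.*$", "", names(set))
  corpus(ids, unname(as.character(set)), provenance)
}

#' Write a corpus to a FASTA file
#'
#' @param x A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- validate_corpus(x)
  lines <- character(0)
  if (nrow(x) > 0L) {
    lines <- as.vector(rbind(paste0(">", x$id), x$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Keep peptides whose length lies within closed bounds
#'
#' @param x A corpus tibble.
#' @param min_len,max_len Inclusive residue-count bounds (defaults 9 and 15,
#'   the training-set range used for model building).
#' @return The filtered corpus, input order preserved.
#' @export
length_filter <- function(x, min_len = 9L, max_len = 15L) {
  x <- validate_corpus(x)
  if (min_len < 1L || min_len > max_len) {
    abort("need 1 <= min_len <= max_len", class = "pepgen_config_error")
  }
  dplyr::filter(x, nchar(.data$sequence) >= min_len,
                nchar(.data$sequence) <= max_len)
}

#' Global-alignment sequence identity between two peptides
#'
#' Needleman-Wunsch global alignment with match score +1, mismatch 0 and a
#' linear gap penalty; identity is the number of matched (identical aligned)
#' positions divided by the length of the shorter sequence, the CD-HIT-style
#' denominator. Symmetric in its arguments.
#'
#' @param a,b Peptide sequences (non-empty, canonical residues).
#' @param gap Linear per-gap-position penalty (positive number, default 1).
#' @param denominator `"shorter"` (default) divides matches by the shorter
#'   sequence length; `"alignment"` divides by the alignment length.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIR") # 8/9
pairwise_identity <- function(a, b, gap = 1,
                              denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  assert_canonical(a)
  assert_canonical(b)
  mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap
  )
  matches <- Biostrings::nmatch(aln)
  denom <- if (denominator == "shorter") min(nchar(a), nchar(b))
           else Biostrings::nchar(aln)
  matches / denom
}

# vectorized identity of one sequence against many (same scoring scheme)
identity_to_many <- function(b, others, gap = 1,
                             denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  mat <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BStringSet(others), b, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = gap
  )
  denom <- if (denominator == "shorter") pmin(nchar(others), nchar(b))
           else Biostrings::nchar(aln)
  Biostrings::nmatch(aln) / denom
}

#' Greedy identity-based redundancy reduction
#'
#' CD-HIT-style greedy incremental clustering: peptides are visited in order
#' of decreasing length (ties broken by id), each joins the first existing
#' cluster whose representative exceeds the identity threshold, otherwise it
#' founds a new cluster. Cluster representatives are returned in the input
#' corpus order.
#'
#' @param x A corpus tibble.
#' @param threshold Identity threshold in `(0, 1]`; a peptide joins a cluster
#'   only when identity with the representative is strictly greater than this
#'   (default 0.9, the redundancy cut used for the training corpus).
#' @param ... Passed to [pairwise_identity()].
#' @return The corpus restricted to cluster representatives.
#' @export
redundancy_reduce <- function(x, threshold = 0.9, ...) {
  x <- validate_corpus(x)
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]", class = "pepgen_config_error")
  }
  if (nrow(x) <= 1L) return(x)
  ord <- order(-nchar(x$sequence), x$id)
  reps <- integer(0)
  for (i in ord) {
    s <- x$sequence[i]
    if (length(reps) > 0L) {
      ident <- identity_to_many(s, x$sequence[reps], ...)
      if (any(ident > threshold)) next
    }
    reps <- c(reps, i)
  }
  dplyr::slice(x, sort(reps))
}

#' The 22-token model vocabulary
#'
#' The 20 canonical amino acids in alphabetical order (indices 0-19), the
#' padding/start token `'X'` (index 20) and the end-of-sequence token `'$'`
#' (index 21). Indices are zero-based to match the encoded-batch convention.
#'
#' @return An object of class `pep_vocabulary` with elements `symbols`
#'   (length 22) and `index` (named integer map, zero-based).
#' @export
pep_vocabulary <- function() {
  symbols <- c(AA20, "X", "$")
  structure(
    list(symbols = symbols,
         index = setNames(seq_along(symbols) - 1L, symbols),
         pad = 20L, eos = 21L),
    class = "pep_vocabulary"
  )
}

#' @export
print.pep_vocabulary <- function(x, ...) {
  cat("<pep_vocabulary> 22 tokens:", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Encode a corpus into padded token windows
#'
#' Each sequence is rendered as `'X'` (start) + residues + `'$'` (end),
#' right-padded with `'X'` to the window length, then mapped to zero-based
#' vocabulary indices. The loss mask is `FALSE` at positions whose
#' next-token prediction target is the padding token (and at the final
#' position, which has no target).
#'
#' @param x A corpus tibble.
#' @param vocab A [pep_vocabulary()].
#' @param window Window length; must be at least the longest sequence plus 2.
#'   Default sizes it to the corpus.
#' @param mask_pad Mask padding targets out of the loss (default `TRUE`).
#' @return A list of class `pep_encoded` with integer matrix `tokens`
#'   (sequences x window, zero-based) and logical matrix `loss_mask`.
#' @export
encode_corpus <- function(x, vocab = pep_vocabulary(), window = NULL,
                          mask_pad = TRUE) {
  x <- validate_corpus(x)
  lens <- nchar(x$sequence)
  if (is.null(window)) window <- if (nrow(x)) max(lens) + 2L else 2L
  if (nrow(x) > 0L && window < max(lens) + 2L) {
    worst <- x$id[which.max(lens)]
    abort(sprintf(
      "window %d too small: peptide '%s' needs %d (length + start + end)",
      window, worst, max(lens) + 2L
    ), class = "pepgen_size_error")
  }
  n <- nrow(x)
  tokens <- matrix(vocab$pad, nrow = n, ncol = window)
  for (i in seq_len(n)) {
    idx <- unname(vocab$index[split_seq(x$sequence[i])])
    tokens[i, seq_along(idx) + 1L] <- idx
    tokens[i, length(idx) + 2L] <- vocab$eos
  }
  mode(tokens) <- "integer"
  # mask[, t] guards the prediction made at input position t (target t+1)
  loss_mask <- matrix(FALSE, nrow = n, ncol = window)
  if (n > 0L && window >= 2L) {
    tgt <- tokens[, -1L, drop = FALSE]
    keep <- if (mask_pad) tgt != vocab$pad else matrix(TRUE, n, window - 1L)
    loss_mask[, seq_len(window - 1L)] <- keep
  }
  structure(list(tokens = tokens, loss_mask = loss_mask, vocab = vocab,
                 ids = x$id),
            class = "pep_encoded")
}

#' Decode token windows back to peptide sequences
#'
#' Inverse of [encode_corpus()]: strips the start token, stops at the first
#' end token, and drops padding.
#'
#' @param batch A `pep_encoded` object, or an integer matrix of zero-based
#'   token indices.
#' @param vocab A [pep_vocabulary()].
#' @return Character vector of sequences.
#' @export
decode_tokens <- function(batch, vocab = pep_vocabulary()) {
  tokens <- if (inherits(batch, "pep_encoded")) batch$tokens else batch
  if (nrow(tokens) == 0L) return(character(0))
  apply(tokens, 1L, function(row) {
    row <- row[-1L]                       # start token
    stop_at <- which(row == vocab$eos)[1]
    if (!is.na(stop_at)) row <- row[seq_len(stop_at - 1L)]
    row <- row[row != vocab$pad]
    paste(vocab$symbols[row + 1L], collapse = "")
  })
}
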