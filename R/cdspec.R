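#' Load a CD basis set from a plain-text matrix
#'
#' Whitespace-delimited text: a header line of secondary-structure class
#' names, then rows of wavelength (nm) followed by one mean-residue
#' ellipticity value per class (deg cm^2 dmol^-1). Rows are re-sorted to an
#' ascending wavelength grid (with a warning if the file is descending).
#'
#' @param path Path to the basis file.
#' @return A list of class `cd_basis`: `wavelengths` (ascending nm grid),
#'   `class_names`, and `basis` (wavelength x class matrix).
#' @export
load_basis <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("basis file '%s' does not exist", path),
          class = "pepgen_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort("basis file needs a header line and at least one data row",
          class = "pepgen_parse_error")
  }
  class_names <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(seq(2L, length(lines)), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(vals) || length(vals) != length(class_names) + 1L) {
      abort(sprintf("basis file line %d: expected wavelength + %d numeric values",
                    i, length(class_names)),
            class = "pepgen_parse_error")
    }
    vals
  })
  m <- do.call(rbind, rows)
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    if (anyDuplicated(m[, 1])) {
      abort("duplicate wavelengths in basis file", class = "pepgen_parse_error")
    }
    warn("basis wavelengths not ascending; rows re-sorted")
    m <- m[order(m[, 1]), , drop = FALSE]
  }
  new_cd_basis(m[, 1], class_names, m[, -1, drop = FALSE])
}

new_cd_basis <- function(wavelengths, class_names, basis) {
  basis <- as.matrix(basis)
  colnames(basis) <- class_names
  stopifnot(all(is.finite(basis)), !is.unsorted(wavelengths, strictly = TRUE))
  structure(list(wavelengths = as.numeric(wavelengths),
                 class_names = class_names, basis = basis),
            class = "cd_basis")
}

#' Write a CD basis set in the plain-text matrix format
#'
#' @param basis A `cd_basis` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "cd_basis"))
  header <- paste(basis$class_names, collapse = " ")
  body <- apply(cbind(basis$wavelengths, basis$basis), 1L, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.cd_basis <- function(x, ...) {
  cat(sprintf("<cd_basis> %d wavelengths (%g-%g nm) x %d classes: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              length(x$class_names), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Secondary-structure composition from a DSSP-style string
#'
#' Maps `H, G, I` to helix, `E, B` to sheet, and everything else
#' (`T, S, C, -`) to coil; fractions sum to 1.
#'
#' @param dssp_like String over `H G I E B T S C -`.
#' @return Named numeric vector `c(helix, sheet, coil)`.
#' @export
ss_from_string <- function(dssp_like) {
  chars <- split_seq(dssp_like)
  known <- c("H", "G", "I", "E", "B", "T", "S", "C", "-")
  bad <- setdiff(unique(chars), known)
  if (length(chars) == 0L || length(bad) > 0L) {
    abort(sprintf("unknown secondary-structure character(s): %s",
                  paste(sprintf("'%s'", bad), collapse = ", ")),
          class = "pepgen_validation_error")
  }
  helix <- mean(chars %in% c("H", "G", "I"))
  sheet <- mean(chars %in% c("E", "B"))
  c(helix = helix, sheet = sheet, coil = 1 - helix - sheet)
}

#' Compute a CD spectrum from a secondary-structure composition
#'
#' Basis-set linear combination: `ellipticity(lambda) = sum_j f_j B_j(lambda)`
#' over the structure classes; linear in the fractions.
#'
#' @param ss Named fractions per class, matching the basis classes; must sum
#'   to 1 within 1e-6.
#' @param basis A `cd_basis`.
#' @return A tibble of class `cd_spectrum` with columns `wavelength` and
#'   `ellipticity`.
#' @export
compute_spectrum <- function(ss, basis) {
  stopifnot(inherits(basis, "cd_basis"))
  if (is.null(names(ss)) || !setequal(names(ss), basis$class_names)) {
    abort(sprintf("composition classes (%s) do not match basis classes (%s)",
                  paste(names(ss), collapse = ", "),
                  paste(basis$class_names, collapse = ", ")),
          class = "pepgen_schema_error")
  }
  if (abs(sum(ss) - 1) > 1e-6 || any(ss < 0 | ss > 1)) {
    abort("structure fractions must lie in [0, 1] and sum to 1",
          class = "pepgen_validation_error")
  }
  ell <- drop(basis$basis[, basis$class_names, drop = FALSE] %*%
                ss[basis$class_names])
  out <- tibble(wavelength = basis$wavelengths, ellipticity = unname(ell))
  class(out) <- c("cd_spectrum", class(out))
  out
}

#' Ellipticity at an arbitrary wavelength
#'
#' Linear interpolation between the bracketing grid points; exact on grid
#' points.
#'
#' @param spectrum A `cd_spectrum` tibble (columns `wavelength`,
#'   `ellipticity`).
#' @param lambda_nm Query wavelength, inside the grid range.
#' @return Mean-residue ellipticity at `lambda_nm`.
#' @export
ellipticity_at <- function(spectrum, lambda_nm) {
  wl <- spectrum$wavelength
  if (lambda_nm < min(wl) || lambda_nm > max(wl)) {
    abort(sprintf("wavelength %g nm outside grid range [%g, %g]",
                  lambda_nm, min(wl), max(wl)),
          class = "pepgen_range_error")
  }
  approx(wl, spectrum$ellipticity, xout = lambda_nm)$y
}

#' Filter candidate spectra against a reference ellipticity
#'
#' Retains candidates whose helical-band signal at `lambda_nm` is at least as
#' strong as the reference's. Under the default sign convention "stronger"
#' means more negative ellipticity at the 220 nm helix band, so candidates
#' with ellipticity above (weaker than) the reference are removed; set
#' `invert = TRUE` for the opposite reading. Order-preserving and
#' deterministic.
#'
#' @param candidates Named list of `cd_spectrum` tibbles (names are peptide
#'   ids).
#' @param reference A `cd_spectrum` tibble.
#' @param lambda_nm Comparison wavelength (default 220).
#' @param invert Invert the sign convention.
#' @return Character vector of surviving candidate ids, in input order.
#' @export
filter_by_reference <- function(candidates, reference, lambda_nm = 220,
                                invert = FALSE) {
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    abort("candidates must be a named list of spectra",
          class = "pepgen_validation_error")
  }
  ref_val <- ellipticity_at(reference, lambda_nm)
  keep <- map_lgl(candidates, function(s) {
    v <- ellipticity_at(s, lambda_nm)
    if (invert) v >= ref_val else v <= ref_val
  })
  names(candidates)[keep]
}
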