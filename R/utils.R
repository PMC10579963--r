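#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_int map_lgl imap
#' @importFrom stats var sd setNames runif rnorm pt approx
NULL

# canonical one-letter amino-acid alphabet, alphabetical order
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# average residue masses (Da); peptide MW = sum + one water
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

split_seq <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

assert_canonical <- function(seq, id = "<sequence>") {
  chars <- split_seq(seq)
  bad <- setdiff(unique(chars), AA20)
  if (nchar(seq) == 0L) {
    abort(sprintf("peptide '%s' has an empty sequence", id),
          class = "pepgen_validation_error")
  }
  if (length(bad) > 0L) {
    abort(sprintf(
      "peptide '%s' contains non-canonical residue(s): %s",
      id, paste(sprintf("'%s'", bad), collapse = ", ")
    ), class = "pepgen_validation_error")
  }
  invisible(seq)
}

pepgen_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepgen")
  if (!nzchar(path)) abort(sprintf("bundled data file '%s' not found", file))
  path
}

.table_cache <- new.env(parent = emptyenv())

cached_table <- function(key, loader) {
  if (!exists(key, envir = .table_cache)) {
    assign(key, loader(), envir = .table_cache)
  }
  get(key, envir = .table_cache)
}

#' Eisenberg consensus hydrophobicity scale
#'
#' Named numeric vector of per-residue consensus hydrophobicities, read from
#' the scale file shipped with the package.
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
eisenberg_scale <- function() {
  cached_table("eisenberg", function() {
    tb <- utils::read.csv(pepgen_extdata("eisenberg_scale.csv"))
    setNames(tb$hydrophobicity, tb$residue)
  })
}

pka_table <- function() {
  cached_table("pka", function() {
    utils::read.csv(pepgen_extdata("pka_sidechains.csv"))
  })
}

diwv_table <- function() {
  cached_table("diwv", function() {
    tb <- utils::read.csv(pepgen_extdata("instability_diwv.csv"),
                          check.names = FALSE)
    m <- as.matrix(tb[, -1])
    rownames(m) <- tb$first
    m
  })
}
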