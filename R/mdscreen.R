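#' Read a multi-model PDB trajectory
#'
#' Parses `MODEL`/`ENDMDL` blocks of fixed-column `ATOM`/`HETATM` records
#' into one frame per model. The atom roster (name, residue, chain order)
#' must be identical across models; a mismatch is a format error naming the
#' model. A file without `MODEL` records is read as a single frame.
#'
#' @param path Path to a PDB file.
#' @return A list of class `pep_trajectory`: `atoms` (tibble with columns
#'   `name`, `element`, `resid`, `resname`, `chain`) and `coords` (array
#'   `frames x atoms x 3`, Angstrom).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file '%s' does not exist", path),
          class = "pepgen_io_error")
  }
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L) {
    abort("no ATOM records found", class = "pepgen_format_error")
  }
  if (length(model_starts) == 0L) {
    groups <- list(`1` = atom_idx)
  } else {
    model_no <- findInterval(atom_idx, model_starts)
    if (any(model_no == 0L)) {
      abort("ATOM records found before the first MODEL",
            class = "pepgen_format_error")
    }
    groups <- split(atom_idx, model_no)
    names(groups) <- vapply(model_starts, function(i) {
      trimws(substr(lines[i], 7, 80))
    }, character(1))[as.integer(names(groups))]
  }
  parse_atoms <- function(idx) {
    ln <- lines[idx]
    tibble(
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resid = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78))
    )
  }
  frames <- lapply(groups, parse_atoms)
  roster <- frames[[1]][c("name", "resname", "chain", "resid")]
  for (i in seq_along(frames)) {
    if (!isTRUE(all.equal(frames[[i]][c("name", "resname", "chain", "resid")],
                          roster, check.attributes = FALSE))) {
      abort(sprintf("atom roster of model %s differs from model %s",
                    names(frames)[i], names(frames)[1]),
            class = "pepgen_format_error")
    }
    if (!all(is.finite(c(frames[[i]]$x, frames[[i]]$y, frames[[i]]$z)))) {
      abort(sprintf("non-finite coordinates in model %s", names(frames)[i]),
            class = "pepgen_format_error")
    }
  }
  n_atoms <- nrow(roster)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3L))
  for (i in seq_along(frames)) {
    coords[i, , ] <- as.matrix(frames[[i]][c("x", "y", "z")])
  }
  atoms <- dplyr::mutate(
    roster,
    element = dplyr::if_else(nzchar(frames[[1]]$element),
                             frames[[1]]$element,
                             substr(gsub("[0-9]", "", roster$name), 1, 1))
  )
  structure(list(atoms = atoms, coords = coords), class = "pep_trajectory")
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A `pep_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pep_trajectory"))
  atoms <- traj$atoms
  n_frames <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    for (a in seq_len(nrow(atoms))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a, atoms$name[a], atoms$resname[a], atoms$chain[a], atoms$resid[a],
        traj$coords[f, a, 1], traj$coords[f, a, 2], traj$coords[f, a, 3],
        1.0, 0.0, atoms$element[a]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.pep_trajectory <- function(x, ...) {
  cat(sprintf("<pep_trajectory> %d frames x %d atoms, chains: %s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Residue-residue contacts between two chains in one frame
#'
#' A residue pair `(i, j)` is in contact when any qualifying atom of residue
#' `i` in `chain_a` lies within `cutoff` (closed threshold, so exactly 4.0 A
#' counts) of any qualifying atom of residue `j` in `chain_b`. Hydrogens are
#' excluded by default.
#'
#' @param traj A `pep_trajectory`.
#' @param frame Frame index.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Distance threshold in Angstrom (default 4.0).
#' @param heavy_only Exclude hydrogen atoms (default `TRUE`).
#' @return Tibble with columns `res_a`, `res_b` (residue indices in
#'   contact), one row per pair.
#' @export
residue_contacts <- function(traj, frame = 1L, chain_a, chain_b,
                             cutoff = 4.0, heavy_only = TRUE) {
  stopifnot(inherits(traj, "pep_trajectory"))
  sel <- function(chain) {
    idx <- which(traj$atoms$chain == chain &
                   (!heavy_only | toupper(traj$atoms$element) != "H"))
    if (length(idx) == 0L) {
      abort(sprintf("chain '%s' not found (or has no qualifying atoms)", chain),
            class = "pepgen_lookup_error")
    }
    idx
  }
  ia <- sel(chain_a)
  ib <- sel(chain_b)
  xa <- traj$coords[frame, ia, , drop = TRUE]
  xb <- traj$coords[frame, ib, , drop = TRUE]
  if (is.null(dim(xa))) xa <- matrix(xa, nrow = 1L)
  if (is.null(dim(xb))) xb <- matrix(xb, nrow = 1L)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  hits <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(tibble(res_a = integer(0), res_b = integer(0)))
  tibble(res_a = traj$atoms$resid[ia[hits[, 1]]],
         res_b = traj$atoms$resid[ib[hits[, 2]]]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$res_a, .data$res_b)
}

#' Per-frame contact-count series between two chains
#'
#' Counts the residue pairs in contact (see [residue_contacts()]) in every
#' frame, optionally restricting the `chain_a` (peptide) side to positively
#' charged residues (Arg, Lys, His).
#'
#' @inheritParams residue_contacts
#' @param selection `"all"` (default) or `"positive"` to keep only R/K/H
#'   residues on the `chain_a` side.
#' @param peptide_id Identifier attached to the series.
#' @return Tibble with columns `peptide_id`, `frame`, `contacts`.
#' @export
contact_series <- function(traj, chain_a, chain_b, cutoff = 4.0,
                           selection = c("all", "positive"),
                           heavy_only = TRUE, peptide_id = "peptide") {
  selection <- match.arg(selection)
  keep_res <- NULL
  if (selection == "positive") {
    pos3 <- c("ARG", "LYS", "HIS")
    keep_res <- unique(traj$atoms$resid[traj$atoms$chain == chain_a &
                                          traj$atoms$resname %in% pos3])
    if (length(keep_res) == 0L) {
      abort(sprintf(
        "positive-residue selection is empty: chain '%s' has no R/K/H residues",
        chain_a), class = "pepgen_config_error")
    }
  }
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    pairs <- residue_contacts(traj, f, chain_a, chain_b, cutoff, heavy_only)
    if (!is.null(keep_res)) pairs <- dplyr::filter(pairs,
                                                   .data$res_a %in% keep_res)
    nrow(pairs)
  }, integer(1))
  tibble(peptide_id = peptide_id, frame = seq_along(counts),
         contacts = counts)
}

#' Contact variance of a per-frame contact series
#'
#' Unbiased sample variance (divisor `n - 1`) of the per-frame contact
#' counts — the screening statistic; zero iff the series is constant.
#'
#' @param counts Integer vector of per-frame contact counts (length >= 2),
#'   or a [contact_series()] tibble.
#' @param population Use the population divisor `n` instead (default
#'   `FALSE`).
#' @return Non-negative variance (dimensionless).
#' @export
#' @examples
#' contact_variance(c(1, 2, 3, 4, 5)) # 2.5
contact_variance <- function(counts, population = FALSE) {
  if (is.data.frame(counts)) counts <- counts$contacts
  n <- length(counts)
  if (n < 2L) {
    abort("contact variance needs at least 2 frames",
          class = "pepgen_stat_error")
  }
  v <- var(counts)
  if (population) v <- v * (n - 1) / n
  v
}

#' Mean and fluctuation of a residue-pair distance across frames
#'
#' Per frame, the minimum heavy-atom distance between the two residues; the
#' mean and standard deviation across frames are returned.
#'
#' @param traj A `pep_trajectory`.
#' @param res_a,res_b `(chain, resid)` pairs given as e.g. `c("A", 3)`.
#' @return Tibble with `mean` and `sd` (Angstrom).
#' @export
distance_stats <- function(traj, res_a, res_b) {
  stopifnot(inherits(traj, "pep_trajectory"))
  pick <- function(spec) {
    idx <- which(traj$atoms$chain == spec[1] &
                   traj$atoms$resid == as.integer(spec[2]) &
                   toupper(traj$atoms$element) != "H")
    if (length(idx) == 0L) {
      abort(sprintf("residue %s:%s not found", spec[1], spec[2]),
            class = "pepgen_lookup_error")
    }
    idx
  }
  ia <- pick(res_a)
  ib <- pick(res_b)
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    xa <- matrix(traj$coords[f, ia, ], ncol = 3L)
    xb <- matrix(traj$coords[f, ib, ], ncol = 3L)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  tibble(mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0)
}

#' Screen peptides by contact variance and binding energy
#'
#' Applies the two selection criteria: contact variance at most
#' `variance_cutoff` (closed inequality) and binding-energy magnitude at
#' least `energy_cutoff_kcal` under the favorable-magnitude convention
#' (an MMPBSA energy of -20 kcal/mol passes a 17 kcal/mol threshold). No
#' record is dropped: every input row returns with its flags; records with
#' missing energies fail the energy criterion and are flagged.
#'
#' @param records Tibble with columns `peptide_id`, `binding_energy`
#'   (kcal/mol) and either `contact_variance` or a `series` list-column of
#'   per-frame counts.
#' @param variance_cutoff Contact-variance cut-off (default 3).
#' @param energy_cutoff_kcal Binding-energy magnitude threshold in kcal/mol
#'   (default 17).
#' @return Tibble with `peptide_id`, `contact_variance`, `binding_energy`,
#'   `passes_variance`, `passes_energy`, `passes_both`, `rank` (assigned by
#'   [rank_top_k()]; `NA` here).
#' @export
screen_peptides <- function(records, variance_cutoff = 3.0,
                            energy_cutoff_kcal = 17.0) {
  if (!"peptide_id" %in% names(records)) {
    abort("records need a 'peptide_id' column", class = "pepgen_schema_error")
  }
  if (!"contact_variance" %in% names(records)) {
    if (!"series" %in% names(records)) {
      abort("records need 'contact_variance' or a 'series' list-column",
            class = "pepgen_schema_error")
    }
    records$contact_variance <- map_dbl(records$series, contact_variance)
  }
  if (!"binding_energy" %in% names(records)) {
    records$binding_energy <- NA_real_
  }
  records |>
    dplyr::mutate(
      passes_variance = .data$contact_variance <= variance_cutoff,
      passes_energy = !is.na(.data$binding_energy) &
        abs(.data$binding_energy) >= energy_cutoff_kcal,
      energy_missing = is.na(.data$binding_energy),
      passes_both = .data$passes_variance & .data$passes_energy,
      rank = NA_integer_
    ) |>
    dplyr::select(dplyr::all_of(c("peptide_id", "contact_variance",
                                  "binding_energy", "passes_variance",
                                  "passes_energy", "energy_missing",
                                  "passes_both", "rank")))
}

#' Rank peptides passing both screening criteria
#'
#' Orders the passing records by most favorable binding energy (largest
#' magnitude first), breaking ties by lower contact variance and then by
#' lexicographic peptide id, and keeps the first `k`.
#'
#' @param screened A [screen_peptides()] result.
#' @param k Number of top candidates (default 20).
#' @return The top-`k` passing records with `rank` 1..k.
#' @export
rank_top_k <- function(screened, k = 20L) {
  if (k <= 0L) {
    abort("k must be positive", class = "pepgen_config_error")
  }
  screened |>
    dplyr::filter(.data$passes_both) |>
    dplyr::arrange(dplyr::desc(abs(.data$binding_energy)),
                   .data$contact_variance, .data$peptide_id) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number())
}

# penetratin cell-penetrating peptide
PENETRATIN <- "RQIKIWFQNRRMKWKK"

#' Fuse a cell-penetrating peptide to a candidate's N-terminus
#'
#' @param seq Candidate peptide sequence.
#' @param cpp Cell-penetrating peptide (default penetratin,
#'   `RQIKIWFQNRRMKWKK`); prepended to `seq`.
#' @return The fused sequence `cpp + seq`.
#' @export
#' @examples
#' fuse_cpp("AAA")
fuse_cpp <- function(seq, cpp = PENETRATIN) {
  assert_canonical(seq)
  if (nzchar(cpp)) assert_canonical(cpp, "cpp")
  paste0(cpp, seq)
}
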