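#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains (D, E, C, Y negative;
#' K, R, H positive) and, optionally, the terminal amine and carboxyl, using
#' the pKa table shipped with the package. Monotone non-increasing in pH.
#'
#' @param seq Canonical peptide sequence.
#' @param pH pH at which to evaluate (default 7.4, physiological).
#' @param include_termini Include N-terminal amine and C-terminal carboxyl
#'   (default `TRUE`).
#' @return Net charge in elementary charges.
#' @export
#' @examples
#' net_charge("RQIKIWFQNRRMKWKK")
net_charge <- function(seq, pH = 7.4, include_termini = TRUE) {
  assert_canonical(seq)
  pk <- pka_table()
  chars <- split_seq(seq)
  counts <- table(factor(chars, levels = pk$group))
  counts <- setNames(as.integer(counts), pk$group)
  if (include_termini) {
    counts["Nterm"] <- 1L
    counts["Cterm"] <- 1L
  }
  charge <- 0
  for (i in seq_len(nrow(pk))) {
    n <- counts[pk$group[i]]
    if (is.na(n) || n == 0L) next
    if (pk$sign[i] > 0) {
      charge <- charge + n / (1 + 10^(pH - pk$pka[i]))
    } else {
      charge <- charge - n / (1 + 10^(pk$pka[i] - pH))
    }
  }
  unname(charge)
}

#' Isoelectric point by bisection
#'
#' Finds the pH in `[0, 14]` at which [net_charge()] vanishes, by bisection
#' to `|charge| < 1e-4`. Deterministic.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, include_termini = TRUE) {
  assert_canonical(seq)
  lo <- 0; hi <- 14
  f_lo <- net_charge(seq, lo, include_termini)
  f_hi <- net_charge(seq, hi, include_termini)
  if (f_lo < 0 || f_hi > 0) {
    abort("net charge does not change sign on pH [0, 14]; pI undefined",
          class = "pepgen_numeric_error")
  }
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- net_charge(seq, mid, include_termini)
    if (abs(f_mid) < 1e-4 || (hi - lo) < 1e-12) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
  }
}

#' Mean Eisenberg hydrophobicity
#'
#' Arithmetic mean of the Eisenberg consensus scale over the residues.
#'
#' @param seq Canonical peptide sequence.
#' @return Mean hydrophobicity in scale units.
#' @export
eisenberg_mean <- function(seq) {
  assert_canonical(seq)
  mean(eisenberg_scale()[split_seq(seq)])
}

#' Eisenberg hydrophobic moment
#'
#' Magnitude of the vector sum of residue hydrophobicities placed at
#' successive `angle`-degree intervals around an ideal helix, normalized by
#' sequence length:
#' `sqrt((sum H_i sin(i * d))^2 + (sum H_i cos(i * d))^2) / N`.
#' A measure of amphipathicity; 100 degrees per residue corresponds to the
#' alpha-helical repeat.
#'
#' @param seq Canonical peptide sequence.
#' @param angle Turn per residue in degrees (default 100).
#' @return Hydrophobic moment in scale units (non-negative).
#' @export
hydrophobic_moment <- function(seq, angle = 100) {
  assert_canonical(seq)
  h <- eisenberg_scale()[split_seq(seq)]
  rad <- (seq_along(h)) * angle * pi / 180
  sqrt(sum(h * sin(rad))^2 + sum(h * cos(rad))^2) / length(h)
}

#' Aromaticity
#'
#' Fraction of residues in `{F, W, Y}`.
#'
#' @param seq Canonical peptide sequence.
#' @return Fraction in `[0, 1]`.
#' @export
aromaticity <- function(seq) {
  assert_canonical(seq)
  chars <- split_seq(seq)
  mean(chars %in% c("F", "W", "Y"))
}

#' Aliphatic index
#'
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with mole-percent
#' compositions `X`.
#'
#' @param seq Canonical peptide sequence.
#' @return Dimensionless index (0 for a sequence with no aliphatic residues).
#' @export
aliphatic_index <- function(seq) {
  assert_canonical(seq)
  chars <- split_seq(seq)
  molpct <- function(a) 100 * mean(chars == a)
  molpct("A") + 2.9 * molpct("V") + 3.9 * (molpct("I") + molpct("L"))
}

#' Instability index
#'
#' `II = (10 / L) * sum` of the Guruprasad dipeptide instability weights
#' (DIWV, shipped as a data file) over adjacent residue pairs. Length-1
#' sequences return 0 by convention.
#'
#' @param seq Canonical peptide sequence.
#' @return Dimensionless index.
#' @export
instability_index <- function(seq) {
  assert_canonical(seq)
  L <- nchar(seq)
  if (L < 2L) return(0)
  chars <- split_seq(seq)
  dw <- diwv_table()
  idx <- cbind(chars[-L], chars[-1L])
  (10 / L) * sum(dw[idx])
}

# default hydrophobic residue set for the hydrophobic ratio
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Hydrophobic ratio
#'
#' Fraction of residues in the configured hydrophobic set.
#'
#' @param seq Canonical peptide sequence.
#' @param set Hydrophobic residue set (default
#'   `A, C, F, I, L, M, V, W, Y`).
#' @return Fraction in `[0, 1]`.
#' @export
hydrophobic_ratio <- function(seq, set = HYDROPHOBIC_SET) {
  assert_canonical(seq)
  mean(split_seq(seq) %in% set)
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq Canonical peptide sequence.
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  assert_canonical(seq)
  sum(AA_MASS[split_seq(seq)]) + WATER_MASS
}

#' Global physicochemical descriptor table for a corpus
#'
#' One row per peptide with the full descriptor panel: length, net charge at
#' `pH`, Eisenberg hydrophobicity and hydrophobic moment, isoelectric point,
#' aromaticity, charge density (charge per Dalton), aliphatic index,
#' instability index and hydrophobic ratio.
#'
#' @param x A corpus tibble.
#' @param pH pH for the charge terms (default 7.4).
#' @return A tibble, one row per peptide, `id` first.
#' @export
describe_peptides <- function(x, pH = 7.4) {
  x <- validate_corpus(x, allow_empty = FALSE)
  dplyr::mutate(
    x,
    length = nchar(.data$sequence),
    charge = map_dbl(.data$sequence, net_charge, pH = pH),
    eisenberg_hydrophobicity = map_dbl(.data$sequence, eisenberg_mean),
    hydrophobic_moment = map_dbl(.data$sequence, hydrophobic_moment),
    isoelectric_point = map_dbl(.data$sequence, isoelectric_point),
    aromaticity = map_dbl(.data$sequence, aromaticity),
    charge_density = .data$charge / map_dbl(.data$sequence, molecular_weight),
    aliphatic_index = map_dbl(.data$sequence, aliphatic_index),
    instability_index = map_dbl(.data$sequence, instability_index),
    hydrophobic_ratio = map_dbl(.data$sequence, hydrophobic_ratio)
  )
}

# the default combined descriptor space used for centroid distances
DISTANCE_FEATURES <- c("charge", "eisenberg_hydrophobicity",
                       "hydrophobic_moment", "length", "isoelectric_point",
                       "aromaticity")

#' Learn min-max scaling parameters from a reference descriptor table
#'
#' @param reference A descriptor tibble (e.g. from [describe_peptides()]).
#' @param features Descriptor columns to scale (default: the six-feature
#'   combined descriptor space of charge, Eisenberg hydrophobicity,
#'   hydrophobic moment, length, isoelectric point and aromaticity).
#' @return A tibble of class `pep_scaling` with columns `feature`, `min`,
#'   `max`; constant reference columns are dropped with a warning.
#' @export
fit_scaling <- function(reference, features = DISTANCE_FEATURES) {
  missing_cols <- setdiff(features, names(reference))
  if (length(missing_cols) > 0L) {
    abort(sprintf("reference table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pepgen_schema_error")
  }
  if (nrow(reference) == 0L) {
    abort("reference table is empty", class = "pepgen_config_error")
  }
  params <- tibble(
    feature = features,
    min = map_dbl(features, ~ min(reference[[.x]])),
    max = map_dbl(features, ~ max(reference[[.x]]))
  )
  const <- params$feature[params$max <= params$min]
  if (length(const) > 0L) {
    warn(sprintf("constant reference column(s) dropped from scaling: %s",
                 paste(const, collapse = ", ")))
    params <- dplyr::filter(params, !.data$feature %in% const)
  }
  class(params) <- c("pep_scaling", class(params))
  params
}

#' Apply (or invert) min-max scaling
#'
#' Scaled value `(x - min) / (max - min)`: the reference set maps into
#' `[0, 1]`; values outside the reference range are not clipped.
#'
#' @param x A descriptor tibble.
#' @param params A [fit_scaling()] result.
#' @param invert Undo the scaling instead (default `FALSE`).
#' @return `x` with the scaled (or unscaled) feature columns.
#' @export
apply_scaling <- function(x, params, invert = FALSE) {
  missing_cols <- setdiff(params$feature, names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf("table lacks scaled column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pepgen_schema_error")
  }
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    rng <- params$max[i] - params$min[i]
    x[[f]] <- if (invert) x[[f]] * rng + params$min[i]
              else (x[[f]] - params$min[i]) / rng
  }
  x
}

#' Euclidean distance to a reference centroid in scaled descriptor space
#'
#' The centroid is the column mean of the scaled reference table; each query
#' row's distance is the L2 norm of its deviation from the centroid over the
#' scaled features.
#'
#' @param scaled_query,scaled_reference Descriptor tibbles already passed
#'   through [apply_scaling()] with the same parameters.
#' @param features Feature columns defining the space (default: those shared
#'   with the scaling step).
#' @return The query tibble with a `centroid_distance` column; the summary
#'   mean and SD are attached as attributes `"mean"` and `"sd"`.
#' @export
euclidean_to_centroid <- function(scaled_query, scaled_reference,
                                  features = DISTANCE_FEATURES) {
  for (tb in list(scaled_query, scaled_reference)) {
    missing_cols <- setdiff(features, names(tb))
    if (length(missing_cols) > 0L) {
      abort(sprintf("descriptor table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "pepgen_schema_error")
    }
  }
  centroid <- colMeans(as.matrix(scaled_reference[features]))
  dev <- sweep(as.matrix(scaled_query[features]), 2L, centroid)
  out <- dplyr::mutate(scaled_query,
                       centroid_distance = sqrt(rowSums(dev^2)))
  attr(out, "mean") <- mean(out$centroid_distance)
  attr(out, "sd") <- sd(out$centroid_distance)
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom, as used
#' to compare descriptor distributions between peptide sets.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values.
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    abort("each sample needs at least 2 values", class = "pepgen_stat_error")
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(tibble(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    }
    abort("both samples have zero variance", class = "pepgen_stat_error")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value))
}

#' Feature-by-feature comparison of two descriptor tables
#'
#' For every feature, the mean and SD in each set and the Welch t, df and
#' two-sided p-value; the layout of a standard generated-vs-reference
#' comparison table.
#'
#' @param a,b Descriptor tibbles (e.g. generated and training sets).
#' @param features Feature columns to compare.
#' @param scaled Compare min-max-scaled values (scaling fit on `b`) instead
#'   of raw values (default `FALSE`).
#' @return Tibble with one row per feature.
#' @export
compare_descriptors <- function(a, b, features = DISTANCE_FEATURES,
                                scaled = FALSE) {
  if (scaled) {
    params <- fit_scaling(b, features)
    features <- params$feature
    a <- apply_scaling(a, params)
    b <- apply_scaling(b, params)
  }
  purrr::map(features, function(f) {
    wt <- welch_ttest(a[[f]], b[[f]])
    tibble(feature = f,
           mean_a = mean(a[[f]]), sd_a = sd(a[[f]]),
           mean_b = mean(b[[f]]), sd_b = sd(b[[f]]),
           t = wt$t, df = wt$df, p = wt$p)
  }) |> purrr::list_rbind()
}
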