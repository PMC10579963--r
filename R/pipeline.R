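pipeline_defaults <- function() {
  list(
    seed = 42L,
    out_dir = "pepgen_run",
    corpus = list(
      fasta = NULL,
      synth_n = 120L,
      motif = "KWLKK",
      length_range = c(9L, 15L),
      min_len = 9L,
      max_len = 15L,
      identity = 0.9
    ),
    model = list(
      layers = 2L,
      units = 256L,
      dropout = c(0.30, 0.45),
      learning_rate = 0.02,
      epochs = 200L,
      batch_size = 128L
    ),
    sample = list(n_draws = 1018L, temperature = 1.0, max_len = 15L),
    compare = list(n_baseline = 200L),
    cd = list(enabled = TRUE, lambda = 220, reference_helix = 0.55,
              reference_sheet = 0.05),
    screen = list(enabled = TRUE, contacts_csv = NULL, energies_csv = NULL,
                  n_frames = 50L, variance_cutoff = 3.0,
                  energy_cutoff = 17.0, top_k = 20L),
    fuse = list(cpp = PENETRATIN)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key '%s'", full),
            class = "pepgen_config_error")
    }
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        abort(sprintf("configuration key '%s' must be a mapping", full),
              class = "pepgen_config_error")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults — identity 0.9,
#' variance cut-off 3, energy threshold 17 kcal/mol, top-20, 220 nm, Adam
#' learning rate 0.02, 30%/45% dropout, 2 x 256 units — and rejects unknown
#' keys by name.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return The normalized configuration list (class `pep_pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("configuration file '%s' does not exist", config),
            class = "pepgen_io_error")
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(pipeline_defaults(), config)
  numeric_one <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("configuration key '%s' must be a single number", key),
            class = "pepgen_config_error")
    }
  }
  numeric_one(cfg$seed, "seed")
  numeric_one(cfg$corpus$identity, "corpus.identity")
  numeric_one(cfg$screen$variance_cutoff, "screen.variance_cutoff")
  numeric_one(cfg$screen$energy_cutoff, "screen.energy_cutoff")
  numeric_one(cfg$screen$top_k, "screen.top_k")
  numeric_one(cfg$cd$lambda, "cd.lambda")
  cfg$corpus$length_range <- as.integer(unlist(cfg$corpus$length_range))
  cfg$model$dropout <- as.numeric(unlist(cfg$model$dropout))
  structure(cfg, class = "pep_pipeline_config")
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path)
  path
}

#' Run the end-to-end design pipeline
#'
#' Executes the stages in order — prepare, train, sample, dedupe,
#' describe/compare, CD filter, contact-variance screen, rank + fuse —
#' writing every intermediate artifact (clean FASTA, checkpoint, sampled and
#' deduplicated FASTA, descriptor and comparison CSVs, CD pass list,
#' screening report, ranked top-k with penetratin-fused sequences) plus a
#' `manifest.json` echoing every seed and threshold actually applied. When
#' no input files are configured, the synthetic generators supply training
#' corpus, contact series and CD basis, so the full pipeline runs with no
#' downloads. Rerunning with the same configuration reproduces all outputs
#' byte-identically.
#'
#' @param config A [validate_config()] result, a list, or a YAML path.
#' @param quiet Suppress per-stage count logging.
#' @return The run directory path, invisibly; the manifest lists artifacts.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "pep_pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(format_version = 1L, config = unclass(cfg),
                   stages = list())
  seed <- as.integer(cfg$seed)

  # -- stage 1: prepare ------------------------------------------------------
  raw <- if (!is.null(cfg$corpus$fasta)) {
    read_fasta(cfg$corpus$fasta, provenance = "training")
  } else {
    synth_corpus(cfg$corpus$synth_n, cfg$corpus$length_range,
                 motif = cfg$corpus$motif, seed = seed)
  }
  kept <- length_filter(raw, cfg$corpus$min_len, cfg$corpus$max_len)
  clean <- redundancy_reduce(kept, cfg$corpus$identity)
  write_fasta(clean, file.path(cfg$out_dir, "clean.fasta"))
  say("prepare: %d -> %d (length) -> %d (identity <= %.2f)",
      nrow(raw), nrow(kept), nrow(clean), cfg$corpus$identity)
  manifest$stages$prepare <- list(n_in = nrow(raw), n_length = nrow(kept),
                                  n_clean = nrow(clean),
                                  artifact = "clean.fasta")

  # -- stage 2: train --------------------------------------------------------
  mcfg <- model_config(layers = cfg$model$layers, units = cfg$model$units,
                       dropout = cfg$model$dropout,
                       learning_rate = cfg$model$learning_rate,
                       epochs = cfg$model$epochs,
                       batch_size = cfg$model$batch_size, seed = seed + 1L)
  model <- train_lstm(clean, mcfg)
  save_checkpoint(model, file.path(cfg$out_dir, "model.ckpt"))
  write_stage_csv(model$trace, cfg$out_dir, "loss_trace.csv")
  say("train: %d epochs, final loss %.4f nats", nrow(model$trace),
      utils::tail(model$trace$train_loss, 1))
  manifest$stages$train <- list(
    epochs = nrow(model$trace),
    final_train_loss = utils::tail(model$trace$train_loss, 1),
    artifact = c("model.ckpt", "loss_trace.csv")
  )

  # -- stage 3 + 4: sample and dedupe ---------------------------------------
  sampled <- sample_peptides(model, cfg$sample$n_draws, cfg$sample$temperature,
                             cfg$sample$max_len, seed = seed + 2L)
  write_fasta(sampled, file.path(cfg$out_dir, "sampled.fasta"))
  generated <- dedupe_against(sampled, clean)
  write_fasta(generated, file.path(cfg$out_dir, "generated.fasta"))
  say("sample: %d draws -> %d valid -> %d unique & novel",
      cfg$sample$n_draws, nrow(sampled), nrow(generated))
  manifest$stages$sample <- list(n_draws = cfg$sample$n_draws,
                                 n_valid = nrow(sampled),
                                 n_unique_novel = nrow(generated),
                                 artifact = c("sampled.fasta",
                                              "generated.fasta"))
  if (nrow(generated) == 0L) {
    abort("pipeline stage 'sample': no unique novel peptides were generated",
          class = "pepgen_stage_error")
  }

  # -- stage 5: describe and compare ----------------------------------------
  nb <- cfg$compare$n_baseline
  len_sampler <- empirical_length_sampler(clean)
  rand <- random_baseline(nb, len_sampler, seed = seed + 3L)
  hel <- helical_baseline(nb, len_sampler, seed = seed + 4L)
  desc <- list(training = describe_peptides(clean),
               generated = describe_peptides(generated),
               random = describe_peptides(rand),
               helical = describe_peptides(hel))
  for (nm in names(desc)) {
    write_stage_csv(desc[[nm]], cfg$out_dir,
                    sprintf("descriptors_%s.csv", nm))
  }
  comparison <- compare_descriptors(desc$generated, desc$training)
  write_stage_csv(comparison, cfg$out_dir, "comparison_table.csv")
  params <- fit_scaling(desc$training)
  ref_scaled <- apply_scaling(desc$training, params)
  dist_summary <- purrr::map(c("generated", "random", "helical"), function(nm) {
    d <- euclidean_to_centroid(apply_scaling(desc[[nm]], params), ref_scaled,
                               features = params$feature)
    tibble(set = nm, mean_distance = attr(d, "mean"),
           sd_distance = attr(d, "sd"), n = nrow(d))
  }) |> purrr::list_rbind()
  write_stage_csv(dist_summary, cfg$out_dir, "centroid_distances.csv")
  say("compare: centroid distance generated %.3f vs random %.3f",
      dist_summary$mean_distance[1], dist_summary$mean_distance[2])
  manifest$stages$compare <- list(
    distances = as.list(setNames(dist_summary$mean_distance,
                                 dist_summary$set)),
    artifact = c("comparison_table.csv", "centroid_distances.csv")
  )

  if (!isTRUE(cfg$cd$enabled)) {
    manifest$artifacts_complete <- FALSE
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("pipeline stopped after the comparison stage (cd disabled)")
    return(invisible(cfg$out_dir))
  }

  # -- stage 6: CD filter ----------------------------------------------------
  # Without a 3-D structure predictor in the loop, per-candidate helical
  # content is estimated from amphipathicity: candidates are assigned a
  # helix fraction increasing in their hydrophobic moment.
  basis <- synth_basis(seed = seed + 5L)
  helix_frac_of <- function(seqs) {
    mu <- vapply(seqs, hydrophobic_moment, numeric(1))
    pmin(0.9, 0.25 + mu)
  }
  cand_ss <- helix_frac_of(generated$sequence)
  spectra <- purrr::map(cand_ss, function(hf) {
    compute_spectrum(c(helix = hf, sheet = 0.05, coil = 0.95 - hf), basis)
  })
  names(spectra) <- generated$id
  ref_spectrum <- compute_spectrum(
    c(helix = cfg$cd$reference_helix, sheet = cfg$cd$reference_sheet,
      coil = 1 - cfg$cd$reference_helix - cfg$cd$reference_sheet), basis)
  readr::write_tsv(ref_spectrum, file.path(cfg$out_dir,
                                           "reference_spectrum.tsv"))
  cd_pass <- filter_by_reference(spectra, ref_spectrum, cfg$cd$lambda)
  writeLines(cd_pass, file.path(cfg$out_dir, "cd_pass.txt"))
  say("cd: %d -> %d at %g nm", nrow(generated), length(cd_pass),
      cfg$cd$lambda)
  manifest$stages$cd <- list(n_in = nrow(generated), n_pass = length(cd_pass),
                             lambda_nm = cfg$cd$lambda,
                             artifact = c("reference_spectrum.tsv",
                                          "cd_pass.txt"))
  if (!isTRUE(cfg$screen$enabled)) {
    manifest$artifacts_complete <- FALSE
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("pipeline stopped after the CD stage (screen disabled)")
    return(invisible(cfg$out_dir))
  }

  # -- stage 7: contact-variance screen -------------------------------------
  if (!is.null(cfg$screen$contacts_csv)) {
    series_tb <- readr::read_csv(cfg$screen$contacts_csv,
                                 show_col_types = FALSE)
    records <- series_tb |>
      dplyr::summarise(series = list(.data$count), .by = "peptide_id")
    energies <- readr::read_csv(cfg$screen$energies_csv,
                                show_col_types = FALSE)
    records <- dplyr::left_join(records, energies, by = "peptide_id")
  } else {
    pool_ids <- utils::head(cd_pass, 127L)
    rec <- synth_contact_records(n_total = length(pool_ids),
                                 n_low_variance = min(57L, length(pool_ids)),
                                 cutoff = cfg$screen$variance_cutoff,
                                 n_frames = cfg$screen$n_frames,
                                 seed = seed + 6L)
    records <- dplyr::mutate(rec, peptide_id = pool_ids)
  }
  screened <- screen_peptides(records, cfg$screen$variance_cutoff,
                              cfg$screen$energy_cutoff)
  write_stage_csv(dplyr::select(screened, -dplyr::any_of("series")),
                  cfg$out_dir, "screening.csv")
  say("screen: %d records, %d pass variance <= %g, %d pass both",
      nrow(screened), sum(screened$passes_variance),
      cfg$screen$variance_cutoff, sum(screened$passes_both))
  manifest$stages$screen <- list(
    n_records = nrow(screened),
    n_pass_variance = sum(screened$passes_variance),
    n_pass_both = sum(screened$passes_both),
    variance_cutoff = cfg$screen$variance_cutoff,
    energy_cutoff_kcal = cfg$screen$energy_cutoff,
    artifact = "screening.csv"
  )

  # -- stage 8: rank and fuse -----------------------------------------------
  top <- rank_top_k(screened, cfg$screen$top_k)
  top <- dplyr::left_join(top, generated[c("id", "sequence")],
                          by = c(peptide_id = "id"))
  top$fused_sequence <- vapply(top$sequence, function(s) {
    if (is.na(s)) NA_character_ else fuse_cpp(s, cpp = cfg$fuse$cpp)
  }, character(1))
  write_stage_csv(top, cfg$out_dir, "top_candidates.csv")
  say("rank: top %d of %d passing; penetratin-fused sequences written",
      nrow(top), sum(screened$passes_both))
  manifest$stages$rank <- list(top_k = cfg$screen$top_k, n_ranked = nrow(top),
                               artifact = "top_candidates.csv")
  manifest$artifacts_complete <- TRUE
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
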