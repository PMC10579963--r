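#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   geom_histogram facet_wrap theme_minimal geom_vline
#' @export
ggplot2::autoplot

#' Plot training and validation loss curves
#'
#' @param object A `pep_lstm` model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pep_lstm <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss") |>
    dplyr::filter(!is.na(.data$loss))
  ggplot(tr, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    labs(x = "epoch", y = "categorical cross-entropy (nats)",
         colour = NULL) +
    theme_minimal()
}

#' Plot fold-averaged validation loss per architecture
#'
#' @param object A `pep_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pep_cv <- function(object, ...) {
  avg <- object$traces |>
    dplyr::summarise(val_loss = mean(.data$val_loss),
                     .by = c("architecture", "epoch"))
  ggplot(avg, aes(x = .data$epoch, y = .data$val_loss,
                  colour = .data$architecture)) +
    geom_line() +
    labs(x = "epoch", y = "mean validation loss (nats)",
         colour = "architecture") +
    theme_minimal()
}

#' Plot a CD spectrum
#'
#' @param object A `cd_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd_spectrum <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$wavelength, y = .data$ellipticity)) +
    geom_line() +
    labs(x = "wavelength (nm)",
         y = expression(paste("mean residue ellipticity (deg ", cm^2,
                              " ", dmol^-1, ")"))) +
    theme_minimal()
}

#' Compare descriptor distributions across peptide sets
#'
#' Faceted histograms of one or more descriptors for corpora of different
#' provenance (training, generated, random, helical).
#'
#' @param descriptors A [describe_peptides()] tibble, or several row-bound
#'   together (the `provenance` column distinguishes the sets).
#' @param features Descriptor columns to show.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_descriptor_distributions <- function(descriptors,
                                          features = DISTANCE_FEATURES,
                                          bins = 30) {
  long <- tidyr::pivot_longer(descriptors, dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$value, fill = .data$provenance)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.5) +
    facet_wrap(~ .data$feature, scales = "free") +
    labs(x = NULL, y = "count", fill = NULL) +
    theme_minimal()
}

#' Plot the contact-variance / binding-energy screening plane
#'
#' Scatter of each record's contact variance against binding energy with the
#' two cut-offs drawn; passing records highlighted.
#'
#' @param screened A [screen_peptides()] result.
#' @param variance_cutoff,energy_cutoff_kcal Thresholds to draw (defaults 3
#'   and 17).
#' @return A ggplot.
#' @export
plot_screening <- function(screened, variance_cutoff = 3.0,
                           energy_cutoff_kcal = 17.0) {
  ggplot(screened, aes(x = .data$contact_variance,
                       y = abs(.data$binding_energy),
                       colour = .data$passes_both)) +
    geom_point() +
    geom_vline(xintercept = variance_cutoff, linetype = 2) +
    ggplot2::geom_hline(yintercept = energy_cutoff_kcal, linetype = 2) +
    labs(x = "contact variance", y = "|binding energy| (kcal/mol)",
         colour = "passes both") +
    theme_minimal()
}
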