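#' Plot motif frequency over selection rounds
#'
#' Step curve of the unique-sequence motif percentage per round (the
#' enrichment readout of a selection campaign), with the abundance-weighted
#' percentage as a dashed companion.
#'
#' @param freq A table from [motif_frequency_by_round()].
#' @return A ggplot.
#' @export
plot_motif_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$round)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$unique_pct,
                                    colour = .data$motif)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$abundance_pct,
                                    colour = .data$motif),
                       linetype = "dashed", alpha = 0.6) +
    ggplot2::labs(x = "selection round",
                  y = "sequences with motif (% of unique)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ld_distribution <- function(object, ...) {
  d <- object$distances
  w <- if (object$weighting == "abundance") d$count else rep(1L, nrow(d))
  ggplot2::ggplot(tibble(distance = rep(d$distance, times = w)),
                  ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$summary$mean,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = sprintf("Damerau-Levenshtein distance to %s",
                              object$reference_name),
                  y = "sequences") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.energy_distribution <- function(object, ...) {
  lab <- if (object$engine == "external-MFE") {
    "minimum free energy (kcal/mol)"
  } else "surrogate energy (-base pairs)"
  ggplot2::ggplot(object$energies, ggplot2::aes(x = .data$energy)) +
    ggplot2::geom_density(fill = "grey70", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$summary$median,
                        linetype = "dotted") +
    ggplot2::labs(x = lab, y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mutation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = attr(object, "mean_rate"),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "core position", y = expression(M[i])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~round, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
  marked <- dplyr::filter(as_tibble(object), !is.na(.data$marker))
  if (nrow(marked)) {
    p <- p + ggplot2::geom_point(data = marked, colour = "red", size = 2,
                                 shape = 18)
  }
  p
}

#' @export
autoplot.binding_fit <- function(object, ...) {
  curve <- object$curve
  g <- curve_geometry(curve)
  # molar ratio (titrant / macromolecule in cell) per injection
  ratio <- molar_ratio(curve)
  dat <- tibble(ratio = ratio, heat = curve$heat_ucal,
                excluded = curve$excluded)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio, y = .data$heat)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "molar ratio", y = "heat per injection (ucal)") +
    ggplot2::theme_minimal()
  if (!object$no_binding) {
    pred <- predict_heats(object, curve)
    p <- p + ggplot2::geom_line(data = tibble(ratio = ratio, heat = pred),
                                colour = "red")
  }
  p
}

molar_ratio <- function(curve) {
  g <- curve_geometry(curve)
  M <- g$cell_conc; X <- 0
  out <- numeric(nrow(curve))
  for (i in seq_len(nrow(curve))) {
    f <- curve$volume_uL[i] / g$cell_volume
    M <- M * (1 - f)
    X <- X * (1 - f) + g$syringe_conc * f
    out[i] <- X / M
  }
  out
}
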