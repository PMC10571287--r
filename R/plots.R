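#' MA plot of two PIS tracks
#'
#' Scatter of M (residual) against A (average level) with the background
#' window shaded and, when a model is given, the fitted robust line.
#'
#' @param ma MA table from [compute_ma()].
#' @param model Optional `daric_norm` fit to overlay.
#' @return A ggplot object.
#' @export
plot_ma <- function(ma, model = NULL) {
  df <- ma[!is.na(ma$M), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "A = (PIS_ref + PIS_other) / 2",
                  y = "M = PIS_ref - PIS_other") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    p <- p + ggplot2::geom_abline(intercept = model$intercept,
                                  slope = model$slope, colour = "red")
  }
  p
}

#' Plot one or more binned tracks along a chromosome
#'
#' @param tracks A named list of per-bin track tibbles (or one tibble).
#' @param chrom Chromosome to show (default: first in the data).
#' @param column Value column.
#' @return A ggplot object, one facet per track.
#' @export
plot_tracks <- function(tracks, chrom = NULL, column = "value") {
  if (is.data.frame(tracks)) tracks <- list(track = tracks)
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  df <- purrr::map_dfr(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    tibble::tibble(track = nm, chrom = tr$chrom,
                   pos = (tr$start + tr$end) / 2, value = tr[[column]])
  })
  if (is.null(chrom)) chrom <- df$chrom[1]
  df <- df[df$chrom == chrom & !is.na(df$value), ]
  df$track <- factor(df$track, levels = names(tracks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$value)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track), scales = "free_y") +
    ggplot2::labs(x = paste0(chrom, " position (Mb)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Emission profile of a differential segmentation
#'
#' Bars of the per-state emission means with +/- 1 sd whiskers; the HMM
#' analogue of an emission heat map.
#'
#' @param object A `daric_hmm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot daric_hmm
#' @export
autoplot.daric_hmm <- function(object, ...) {
  df <- tidy.daric_hmm(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "emission mean of residual PIS") +
    ggplot2::theme_minimal()
}

#' Variability landscape of a panel segmentation
#'
#' Scatter of per-bin (mean, sd) of PIS coloured by assigned state, with
#' the state emission centres marked.
#'
#' @param object A `daric_varhmm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot daric_varhmm
#' @export
autoplot.daric_varhmm <- function(object, ...) {
  st <- object$states
  ggplot2::ggplot(st, ggplot2::aes(x = .data$mean, y = .data$sd,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_point(data = object$emissions,
                        ggplot2::aes(x = .data$mean_pis, y = .data$sd_pis),
                        colour = "black", shape = 4, size = 3) +
    ggplot2::labs(x = "panel mean PIS", y = "panel sd of PIS",
                  colour = "state") +
    ggplot2::theme_minimal()
}
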