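#' Plot a first-passage distribution with its fitted background
#'
#' Log-scale plot of first-passage counts against separation for one
#' (anchor, target, direction), with the fitted exponential background
#' overlaid; peaks stand out as points far above (or below) the line.
#'
#' @param fp First-passage counts from [count_all_pairs()].
#' @param fits Background fits from [fit_backgrounds()].
#' @param x,y Amino-acid pair to plot.
#' @param direction Scan direction.
#' @param l_max Largest separation displayed.
#' @return A ggplot object.
#' @export
plot_first_passage <- function(fp, fits, x, y, direction = "N", l_max = 60L) {
  check_aa(x); check_aa(y); check_direction(direction)
  d <- dplyr::filter(fp, .data$x == !!x, .data$y == !!y,
                     .data$direction == !!direction, .data$L <= l_max)
  f <- dplyr::filter(fits, .data$x == !!x, .data$y == !!y,
                     .data$direction == !!direction)
  if (nrow(d) == 0L) stop("no counts for pair ", x, y, " (", direction, ")",
                          call. = FALSE)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$L, y = .data$count)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "separation L (residues)",
      y = "number of first passages",
      title = paste0(x, " → ", y, " (", direction, "-terminal direction)")
    ) +
    ggplot2::theme_minimal()
  if (nrow(f) == 1L && isTRUE(f$valid)) {
    line <- tibble::tibble(L = seq_len(l_max),
                           count = exp(f$intercept - f$lambda * seq_len(l_max)))
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}

#' Plot OGT against peak log-amplitude across organisms
#'
#' Scatter of optimal growth temperature against the log-amplitude `q` of a
#' chosen peak across organisms, with hyperthermophiles (OGT above 60 degC)
#' highlighted.
#'
#' @param data A data frame with one row per organism, containing the
#'   amplitude and OGT columns (e.g. a filtered slice of a scan's `scores`
#'   joined to its metadata).
#' @param q_col,ogt_col Column names.
#' @param thermophile_cutoff OGT (degC) above which points are highlighted.
#' @return A ggplot object.
#' @export
plot_ogt_dependence <- function(data, q_col = "q", ogt_col = "ogt_celsius",
                                thermophile_cutoff = 60) {
  d <- tibble::tibble(q = data[[q_col]], ogt = data[[ogt_col]])
  d$group <- ifelse(d$ogt > thermophile_cutoff, "hyperthermophile", "other")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$ogt,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(hyperthermophile = "red", other = "blue"), guide = "none") +
    ggplot2::labs(x = "peak log-amplitude q", y = "OGT (°C)") +
    ggplot2::theme_minimal()
}

#' Autoplot method for scan results
#'
#' Plots OGT against `q` for the top retained pair of a scan (or a chosen
#' pair).
#'
#' @param object An `fp_scan_result` from [run_scan()].
#' @param x,y,direction,L Optional pair selection; defaults to the retained
#'   modal pair with the largest `|q_bar|`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fp_scan_result <- function(object, x = NULL, y = NULL,
                                    direction = NULL, L = NULL, ...) {
  modal <- dplyr::filter(object$pair_summary, .data$is_modal)
  if (is.null(x)) {
    if (nrow(modal) == 0L) stop("no retained pairs to plot", call. = FALSE)
    top <- modal[which.max(abs(modal$q_bar)), ]
    x <- top$x; y <- top$y; direction <- top$direction; L <- top$L
  }
  d <- object$scores |>
    dplyr::filter(.data$x == !!x, .data$y == !!y,
                  .data$direction == !!direction, .data$L == !!L,
                  .data$defined) |>
    dplyr::inner_join(dplyr::select(object$metadata, "organism_id",
                                    "ogt_celsius"),
                      by = "organism_id")
  plot_ogt_dependence(d) +
    ggplot2::ggtitle(paste0(x, " → ", y, " at L = ", L,
                            " (", direction, ")"))
}
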