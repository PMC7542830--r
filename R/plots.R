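#' Plot a PGLS allometric fit
#'
#' Scatter of the (log10) data with the PGLS regression line. Only simple
#' (single continuous predictor) fits are drawn.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  vars <- all.vars(object$formula)
  if (length(vars) != 2) {
    stop("autoplot supports simple y ~ x fits only", call. = FALSE)
  }
  df <- object$model_frame
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[vars[2]]],
                                   y = .data[[vars[1]]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2]) +
    ggplot2::labs(
      title = sprintf("PGLS: slope = %.2f, lambda = %.2f, R2 = %.2f",
                      object$coefficients[2], object$lambda,
                      object$r_squared),
      x = vars[2], y = vars[1]) +
    ggplot2::theme_minimal()
}

#' Plot investment factors by ecological state
#'
#' Jittered investment factors per state with mean (diamond) and median
#' (bar), on a log axis so factors above and below 1 are symmetric.
#'
#' @param object An `investment_tbl` with the trait column attached.
#' @param trait Name of the ecological trait column (default
#'   `adult_habitat`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot investment_tbl
#' @export
autoplot.investment_tbl <- function(object, trait = "adult_habitat", ...) {
  if (!trait %in% names(object)) {
    stop("trait column not in investment table: ", trait, call. = FALSE)
  }
  df <- dplyr::filter(object, !is.na(.data[[trait]]), .data[[trait]] != "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[trait]],
                                   y = .data$investment,
                                   colour = .data[[trait]])) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 4, colour = "black") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "black",
                          linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(y = "eye investment (x predicted)", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Compare allometric slopes across clades
#'
#' Dot plot of fitted slopes per clade and comparison from
#' [batch_clade_fits()], PGLS and OLS side by side.
#'
#' @param table A `CladeScalingTable` tibble from [batch_clade_fits()].
#' @return A ggplot object.
#' @export
plot_clade_slopes <- function(table) {
  df <- dplyr::filter(table, is.na(.data$error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope, y = .data$clade,
                                   colour = .data$method)) +
    ggplot2::geom_point(size = 2, position =
                          ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "allometric slope", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
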