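#' @importFrom broom tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> velocity %.1f +/- %.1f nt/s (N = %d, %g nt/s bins)\n",
    x$mean_nt_s, x$sd_nt_s, x$n, x$bin_width_nt_s))
  invisible(x)
}

#' Tidy methods for curtainr fit objects
#'
#' [broom::tidy()] returns one row per parameter; [broom::glance()] returns
#' a one-row summary.
#'
#' @param x A `gaussian_fit`, `survival_fit`, `coloc_result` or `rate_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name curtainr-tidiers
NULL

#' @rdname curtainr-tidiers
#' @exportS3Method broom::tidy
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mean_nt_s", "sd_nt_s", "amplitude"),
    estimate = c(x$mean_nt_s, x$sd_nt_s, x$amplitude)
  )
}

#' @rdname curtainr-tidiers
#' @exportS3Method broom::glance
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(mean_nt_s = x$mean_nt_s, sd_nt_s = x$sd_nt_s,
                 amplitude = x$amplitude, bin_width_nt_s = x$bin_width_nt_s,
                 n = x$n, method = x$method %||% "histogram")
}

#' @export
print.survival_fit <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" [%.2f, %.2f]", x$ci_low, x$ci_high)
  cat(sprintf("<survival_fit> half-life %.2f knt%s (N = %d)\n",
              x$halflife_knt, ci, x$n))
  invisible(x)
}

#' @rdname curtainr-tidiers
#' @exportS3Method broom::tidy
tidy.survival_fit <- function(x, ...) {
  tibble::tibble(
    term = "halflife_knt", estimate = x$halflife_knt,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @rdname curtainr-tidiers
#' @exportS3Method broom::glance
glance.survival_fit <- function(x, ...) {
  tibble::tibble(halflife_knt = x$halflife_knt,
                 decay_rate_per_knt = x$decay_rate_per_knt,
                 ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d%% colocalized (N = %d/%d) [%.2f, %.2f]\n",
              x$percent, x$n_coloc, x$n_total, x$ci_low, x$ci_high))
  invisible(x)
}

#' @rdname curtainr-tidiers
#' @exportS3Method broom::glance
glance.coloc_result <- function(x, ...) {
  tibble::tibble(n_coloc = x$n_coloc, n_total = x$n_total,
                 fraction = x$fraction, percent = x$percent,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> kcat %.3g +/- %.2g s^-1 (%d points)\n",
              x$kcat_s, x$se_kcat_s, x$n_points))
  invisible(x)
}

#' @rdname curtainr-tidiers
#' @exportS3Method broom::glance
glance.rate_fit <- function(x, ...) {
  tibble::tibble(kcat_s = x$kcat_s, se_kcat_s = x$se_kcat_s,
                 rate_frac_per_s = x$rate_frac_per_s, n_points = x$n_points)
}

# ---- plots -----------------------------------------------------------------

#' Plot methods
#'
#' `autoplot()` turns curtainr objects into ggplot2 figures: a velocity
#' histogram with its Gaussian fit overlaid, a survival curve with its
#' exponential fit, or a two-colour kymograph image.
#'
#' @param object A `gaussian_fit`, `survival_fit` or `kymograph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name curtainr-autoplot
NULL

#' @rdname curtainr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.gaussian_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(0, max(object$histogram$hi), length.out = 200))
  grid$y <- object$amplitude *
    (pnorm((grid$x + object$bin_width_nt_s / 2 - object$mean_nt_s) / object$sd_nt_s) -
       pnorm((pmax(grid$x - object$bin_width_nt_s / 2, object$detection_floor) -
                object$mean_nt_s) / object$sd_nt_s))
  ggplot2::ggplot(object$histogram) +
    ggplot2::geom_col(ggplot2::aes(x = .data$mid, y = .data$count),
                      fill = "grey70", colour = "grey30", width = object$bin_width_nt_s) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "darkgreen", linewidth = 1) +
    ggplot2::labs(x = "velocity (nt/s)", y = "count",
                  title = sprintf("%.1f +/- %.1f nt/s (N = %d)",
                                  object$mean_nt_s, object$sd_nt_s, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname curtainr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.survival_fit <- function(object, ...) {
  grid <- tibble::tibble(
    d = seq(0, max(object$curve$distance_nt), length.out = 200))
  grid$S <- exp(-grid$d * log(2) / (object$halflife_knt * 1000))
  ggplot2::ggplot(object$curve) +
    ggplot2::geom_step(ggplot2::aes(x = .data$distance_nt / 1000,
                                    y = .data$surviving)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$d / 1000, y = .data$S),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "distance (knt)", y = "survival probability",
                  title = sprintf("half-life %.2f knt (N = %d)",
                                  object$halflife_knt, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname curtainr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$position_nt / 1000,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "position (knt, tether at 0)") +
    ggplot2::theme_minimal()
}
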