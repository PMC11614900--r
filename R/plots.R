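#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a polarization map
#'
#' Heatmap of (damped) 15N polarization over the sequence delays, the
#' simulation analogue of the experimental SOT optimization maps.
#'
#' @param object A [sot_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sot_map
#' @export
autoplot.sot_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tau1_s * 1e3, .data$tau2_s * 1e3,
                                       fill = .data$polarization * 100)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(15N) [%]") +
    ggplot2::labs(
      x = expression(tau[1] ~ "[ms]"), y = expression(tau[2] ~ "[ms]"),
      title = sprintf("%s, k_d = %.3g /s", attr(object, "sequence"),
                      attr(object, "k_d"))) +
    ggplot2::theme_minimal()
}

#' Plot exchange kinetics with the fitted curves
#'
#' @param object A `biexp_fit` or `exchange_fit`.
#' @param ... Unused.
#' @return A ggplot of the bound and free 15N signals vs mixing time with
#'   the fitted model overlaid.
#' @method autoplot biexp_fit
#' @export
autoplot.biexp_fit <- function(object, ...) {
  d <- object$data
  tt <- seq(min(d$tau_e_s), max(d$tau_e_s), length.out = 200)
  a <- object$amplitudes
  fit <- tibble::tibble(
    tau_e_s = rep(tt, 2),
    value = c(biexp_eval(tt, object$R, object$k, a["A_e"], a["B_e"], a["C_e"]),
              biexp_eval(tt, object$R, object$k, a["A_f"], a["B_f"], a["C_f"])),
    pool = rep(c("bound (M_e)", "free (M_f)"), each = length(tt)))
  pts <- tidyr::pivot_longer(d[, c("tau_e_s", "M_e", "M_f")],
                             cols = c("M_e", "M_f"),
                             names_to = "pool", values_to = "value")
  pts$pool <- ifelse(pts$pool == "M_e", "bound (M_e)", "free (M_f)")
  ggplot2::ggplot(pts, ggplot2::aes(.data$tau_e_s, .data$value,
                                    colour = .data$pool)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit) +
    ggplot2::labs(x = expression(tau[e] ~ "[s]"), y = "15N signal [a.u.]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.biexp_fit
#' @method autoplot exchange_fit
#' @export
autoplot.exchange_fit <- function(object, ...) {
  if (object$model == "eigen") return(autoplot.biexp_fit(object$biexp, ...))
  d <- object$data
  tt <- seq(min(d$tau_e_s), max(d$tau_e_s), length.out = 200)
  sys <- exchange_system(k_d = object$k_d, c_complex = 4,
                         c_free = 4 / object$ratio, R_e = object$R)
  sim <- simulate_model(object$model, sys, tt, object$P_e0)
  fit <- tibble::tibble(
    tau_e_s = rep(tt, 2), value = c(sim$M_e, sim$M_f),
    pool = rep(c("bound (M_e)", "free (M_f)"), each = length(tt)))
  pts <- tidyr::pivot_longer(d[, c("tau_e_s", "M_e", "M_f")],
                             cols = c("M_e", "M_f"),
                             names_to = "pool", values_to = "value")
  pts$pool <- ifelse(pts$pool == "M_e", "bound (M_e)", "free (M_f)")
  ggplot2::ggplot(pts, ggplot2::aes(.data$tau_e_s, .data$value,
                                    colour = .data$pool)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit) +
    ggplot2::labs(x = expression(tau[e] ~ "[s]"), y = "15N signal [a.u.]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Eyring plot
#'
#' `ln(k_d / T)` against `1/T` with the weighted linear fit.
#'
#' @param object An `eyring_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eyring_fit
#' @export
autoplot.eyring_fit <- function(object, ...) {
  d <- object$data
  d$x <- 1 / d$temperature_K
  d$y <- log(d$kd_per_s / d$temperature_K)
  xg <- seq(min(d$x), max(d$x), length.out = 100)
  cf <- stats::coef(object$lm)
  line <- tibble::tibble(x = xg, y = cf[1] + cf[2] * xg)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::labs(x = "1/T [1/K]", y = "ln(k_d / T)",
                  subtitle = sprintf(
                    "dH = %.1f kJ/mol, dS = %.1f J/(mol K)",
                    object$dH, object$dS)) +
    ggplot2::theme_minimal()
}
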