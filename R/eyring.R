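#' Eyring rate equation
#'
#' Transition-state-theory rate
#' `k_d(T) = (k_B T / h) exp(dS / R_gas) exp(-dH / (R_gas T))`
#' with transmission coefficient 1.
#'
#' @param T Temperature(s), K (> 0).
#' @param dH Activation enthalpy, kJ/mol.
#' @param dS Activation entropy, J mol^-1 K^-1.
#' @return Rate constant(s), s^-1.
#' @examples
#' eyring_rate(298, 0, 0) # k_B T / h, about 6.21e12
#' @export
eyring_rate <- function(T, dH, dS) {
  if (any(T <= 0)) stop("temperature must be positive")
  cst <- physical_constants()
  (cst$k_B * T / cst$h) * exp(dS / cst$R_gas) *
    exp(-dH * 1e3 / (cst$R_gas * T))
}

#' Eyring analysis of temperature-dependent dissociation rates
#'
#' Weighted linear regression of `ln(k_d / T)` on `1/T`:
#' slope `= -dH/R_gas`, intercept `= ln(k_B/h) + dS/R_gas`. Weights are
#' `(k_d / sigma_kd)^2`, the inverse variances of `ln k_d` propagated as
#' `sigma_ln = sigma_kd / k_d`. Covariance comes from the weighted fit.
#'
#' @param data Tibble/data frame with columns `temperature_K`, `kd_per_s`,
#'   and optionally `sigma_kd` (unweighted fit when absent or zero).
#' @return Object of class `eyring_fit` with `dH` (kJ/mol), `dS`
#'   (J mol^-1 K^-1), their standard errors, covariance, and the fitted lm.
#' @export
fit_eyring <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("temperature_K", "kd_per_s") %in% names(data))) {
    stop("data must contain temperature_K and kd_per_s")
  }
  Tk <- data$temperature_K
  kd <- data$kd_per_s
  if (length(unique(Tk)) < 3) stop("need at least 3 distinct temperatures")
  if (diff(range(Tk)) <= 0) stop("zero spread in temperature")
  if (any(kd <= 0)) stop("rate constants must be positive")
  w <- if ("sigma_kd" %in% names(data) && all(data$sigma_kd > 0)) {
    (kd / data$sigma_kd)^2
  } else {
    rep(1, length(kd))
  }
  cst <- physical_constants()
  y <- log(kd / Tk)
  x <- 1 / Tk
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  dH <- -cf[["x"]] * cst$R_gas / 1e3
  dS <- (cf[["(Intercept)"]] - log(cst$k_B / cst$h)) * cst$R_gas
  # linear map (dH, dS) = M (slope, intercept) + const
  sigma_dH <- sqrt(V["x", "x"]) * cst$R_gas / 1e3
  sigma_dS <- sqrt(V["(Intercept)", "(Intercept)"]) * cst$R_gas
  cov_dHdS <- -V["x", "(Intercept)"] * cst$R_gas^2 / 1e3
  structure(
    list(dH = dH, dS = dS, sigma_dH = sigma_dH, sigma_dS = sigma_dS,
         cov = matrix(c(sigma_dH^2, cov_dHdS, cov_dHdS, sigma_dS^2), 2, 2,
                      dimnames = list(c("dH", "dS"), c("dH", "dS"))),
         transmission = 1, lm = fit, data = tibble::as_tibble(data)),
    class = "eyring_fit"
  )
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat(sprintf("<eyring_fit> dH = %.3g +/- %.2g kJ/mol, dS = %.3g +/- %.2g J/(mol K)\n",
              x$dH, x$sigma_dH, x$dS, x$sigma_dS))
  invisible(x)
}

#' @method tidy eyring_fit
#' @export
tidy.eyring_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH_kJ_mol", "dS_J_mol_K"),
    estimate = c(x$dH, x$dS),
    std.error = c(x$sigma_dH, x$sigma_dS)
  )
}

#' @method glance eyring_fit
#' @export
glance.eyring_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = nrow(x$data))
}

#' Inverse-variance weighted mean of rate constants
#'
#' `mean = sum(k_i / s_i^2) / sum(1 / s_i^2)`,
#' `sigma = (sum(1 / s_i^2))^(-1/2)` — the model-averaged dissociation rate.
#'
#' @param values Rate constants.
#' @param sigmas Standard errors (same length, positive; a single value may
#'   have sigma 0 and is returned as-is).
#' @return One-row tibble with `mean` and `sigma`.
#' @examples
#' weighted_mean_kd(c(8, 10), c(0.1, 0.3))
#' @export
weighted_mean_kd <- function(values, sigmas) {
  stopifnot(length(values) == length(sigmas))
  if (length(values) == 1) {
    return(tibble::tibble(mean = values, sigma = sigmas))
  }
  if (any(sigmas <= 0)) stop("all sigmas must be positive")
  w <- 1 / sigmas^2
  tibble::tibble(mean = sum(values * w) / sum(w), sigma = 1 / sqrt(sum(w)))
}

#' Thermal equilibrium polarization and signal enhancement
#'
#' `thermal_polarization()` returns the Boltzmann polarization
#' `P_th = tanh(hbar |gamma| B0 / (2 k_B T))` of a spin-1/2 nucleus;
#' `enhancement()` is the ratio of a hyperpolarized level to it.
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1 (sign ignored).
#' @param B0 Field, T.
#' @param T Temperature, K.
#' @param P Polarization (fraction).
#' @param P_th Thermal polarization (fraction).
#' @return Polarization fraction / enhancement factor.
#' @examples
#' P_th <- thermal_polarization(physical_constants()$gamma_15N, 9.4, 298)
#' enhancement(0.01, P_th)
#' @export
thermal_polarization <- function(gamma, B0, T) {
  if (any(B0 <= 0) || any(T <= 0)) stop("B0 and T must be positive")
  cst <- physical_constants()
  tanh(cst$hbar * abs(gamma) * B0 / (2 * cst$k_B * T))
}

#' @rdname thermal_polarization
#' @export
enhancement <- function(P, P_th) P / P_th
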