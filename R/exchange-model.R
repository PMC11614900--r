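#' Describe a substrate-exchange system
#'
#' Parameters of the reversible ligand exchange between the SABRE complex
#' C_S S_2 (two equatorial substrate ligands) and free substrate S. The
#' complex loses a ligand at total rate `k_d`, so the complex lifetime is
#' `1/k_d` and a chosen single ligand dissociates at `k_d/2`.
#'
#' @param k_d Dissociation rate constant, s^-1 (> 0 for exchange).
#' @param c_complex Complex concentration \[C_S S_2\], mM.
#' @param c_free Free substrate concentration \[S\], mM.
#' @param R_e Longitudinal relaxation rate of bound 15N, s^-1.
#' @param R_f Longitudinal relaxation rate of free 15N, s^-1. Defaults to
#'   `R_e` (one shared effective relaxation rate).
#' @param k_assoc Pseudo-first-order re-association rate for the three-pool
#'   model, s^-1. Default `20 * k_d` (fast re-association).
#' @return An object of class `exchange_system`.
#' @examples
#' exchange_system(k_d = 8, c_complex = 4, c_free = 48.96, R_e = 0.07)
#' @export
exchange_system <- function(k_d, c_complex, c_free, R_e, R_f = R_e,
                            k_assoc = NULL) {
  if (k_d < 0 || R_e < 0 || R_f < 0) stop("rates must be non-negative")
  if (c_complex <= 0 || c_free <= 0) stop("concentrations must be positive")
  if (is.null(k_assoc)) k_assoc <- 20 * k_d
  if (k_assoc < 0) stop("k_assoc must be non-negative")
  structure(
    list(k_d = k_d, c_complex = c_complex, c_free = c_free,
         R_e = R_e, R_f = R_f, k_assoc = k_assoc,
         ratio = c_complex / c_free),
    class = "exchange_system"
  )
}

#' @export
print.exchange_system <- function(x, ...) {
  cat(sprintf(
    "<exchange_system> k_d = %.4g /s (lifetime %.3g s), r = [C]/[S] = %.4g\n",
    x$k_d, 1 / x$k_d, x$ratio))
  cat(sprintf("R_e = %.4g /s, R_f = %.4g /s, k_assoc = %.4g /s\n",
              x$R_e, x$R_f, x$k_assoc))
  invisible(x)
}

#' First-order rate matrix of an exchange model
#'
#' Generator of the longitudinal-magnetization kinetics, `dM/dt = L M`.
#'
#' The `"simplified"` two-pool model (C_S S_2 <-> S_2) tracks the bound
#' (`M_e`) and free (`M_f`) magnetization:
#' \deqn{dM_e/dt = -(R_e + k_d/2) M_e + k_d r M_f}
#' \deqn{dM_f/dt = (k_d/2) M_e - (R_f + k_d r) M_f}
#' with `r = c_complex / c_free`. With equal relaxation rates its eigenvalues
#' are `-R` and `-(R + k)` with `k = k_d (0.5 + r)`, the relation used by the
#' eigenvalue analysis.
#'
#' The `"full"` three-pool model (C_S S_2 <-> C_S S + S) adds the
#' intermediate mono-substrate complex: a bound, magnetized ligand moves to
#' the intermediate pool when its partner dissociates (rate `k_d/2`), returns
#' to the bound pool on re-association (rate `k_assoc`), and the free pool
#' exchanges with the intermediate's vacancy at the matched equilibrium flux
#' (`c_CSS = k_d c_complex / k_assoc` by detailed balance). It reduces to the
#' simplified model as `k_assoc -> Inf`.
#'
#' @param model `"simplified"` or `"full"`.
#' @param system An [exchange_system()].
#' @return Square numeric matrix (2x2 or 3x3) with pool names
#'   (`M_e`, `M_f`, and `M_i` for the intermediate).
#' @export
rate_matrix <- function(model = c("simplified", "full"), system) {
  model <- match.arg(model)
  stopifnot(inherits(system, "exchange_system"))
  kd <- system$k_d; r <- system$ratio
  if (model == "simplified") {
    L <- matrix(c(
      -(system$R_e + kd / 2),  kd * r,
      kd / 2,                 -(system$R_f + kd * r)
    ), 2, 2, byrow = TRUE)
    dimnames(L) <- list(c("M_e", "M_f"), c("M_e", "M_f"))
  } else {
    ka <- system$k_assoc
    c_css <- kd * system$c_complex / ka
    kfree <- ka * c_css / system$c_free   # = kd * c_complex / c_free
    L <- matrix(c(
      -(system$R_e + kd), ka,                  kfree,
      kd / 2,            -(system$R_e + ka),   0,
      kd / 2,             0,                  -(system$R_f + kfree)
    ), 3, 3, byrow = TRUE)
    dimnames(L) <- list(c("M_e", "M_i", "M_f"), c("M_e", "M_i", "M_f"))
  }
  L
}

# matrix exponential of a small real matrix via eigendecomposition, with a
# scaled Taylor-series fallback for (near-)defective cases
expm_small <- function(A, t = 1) {
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev) && all(is.finite(ev$values))) {
    V <- ev$vectors
    rc <- tryCatch(rcond(abs(V)), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-10) {
      out <- V %*% diag(exp(ev$values * t), nrow(A)) %*% solve(V)
      return(Re(out))
    }
  }
  # series with scaling and squaring
  nsq <- max(0, ceiling(log2(max(1, max(abs(A)) * abs(t)))))
  B <- A * (t / 2^nsq)
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:30) {
    term <- term %*% B / k
    E <- E + term
  }
  for (k in seq_len(nsq)) E <- E %*% E
  E
}

#' Simulate exchange kinetics of hyperpolarized magnetization
#'
#' Matrix-exponential solution of `dM/dt = L M` on the mixing-time grid,
#' starting from bound polarization `P_e0` with the free pool (and the
#' intermediate pool, for the full model) at zero — at `tau_e = 0` the free
#' substrate is unpolarized.
#'
#' @param model `"simplified"` or `"full"`.
#' @param system An [exchange_system()].
#' @param tau_e Numeric vector of mixing times, s.
#' @param P_e0 Initial bound magnetization (> 0). Default 1.
#' @return Tibble with columns `tau_e_s`, `M_e`, `M_f` (and `M_i` for the
#'   full model).
#' @export
simulate_model <- function(model = c("simplified", "full"), system, tau_e,
                           P_e0 = 1) {
  model <- match.arg(model)
  if (!all(is.finite(tau_e)) || any(tau_e < 0)) {
    stop("tau_e must be finite and non-negative")
  }
  if (!is.finite(P_e0) || P_e0 <= 0) stop("P_e0 must be positive")
  L <- rate_matrix(model, system)
  ev <- eigen(L)
  V <- ev$vectors; Vi <- solve(V)
  m0 <- c(P_e0, rep(0, nrow(L) - 1))
  coef <- Vi %*% m0
  M <- vapply(tau_e, function(t) {
    Re(V %*% (exp(ev$values * t) * coef))[, 1]
  }, numeric(nrow(L)))
  out <- tibble::tibble(tau_e_s = tau_e, M_e = M[1, ],
                        M_f = M[nrow(L), ])
  if (model == "full") out$M_i <- M[2, ]
  out
}
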