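#' Define a spin-1/2 system for spin-order-transfer simulation
#'
#' A spin system is an ordered set of spin-1/2 nuclei, each assigned to an RF
#' channel (`"H"` for 1H, `"N"` for 15N), together with the scalar-coupling
#' network in Hz and optional rotating-frame offsets. Couplings between spins
#' on the same channel are treated as full isotropic scalar couplings (the
#' hydrides are chemically equivalent and strongly coupled); heteronuclear
#' couplings are truncated to their secular zz part, as appropriate at high
#' field.
#'
#' @param labels Character vector of spin labels, e.g. `c("H1", "H2", "N1")`.
#' @param channels Character vector the same length as `labels`, each `"H"` or
#'   `"N"`. Defaults to the first letter of each label.
#' @param couplings Symmetric numeric matrix of scalar couplings J_ij in Hz
#'   (signed), with zero diagonal. Missing (`NULL`) means all zero.
#' @param offsets Numeric vector of per-spin rotating-frame offsets in Hz.
#'   Default 0 (all pulses on resonance).
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system_preset("threeSpin")
#' sys$couplings["H1", "N1"]
#' @seealso [spin_system_preset()] for the built-in SABRE systems.
#' @export
spin_system <- function(labels, channels = NULL, couplings = NULL,
                        offsets = 0) {
  stopifnot(is.character(labels), length(labels) >= 1)
  if (anyDuplicated(labels)) stop("spin labels must be unique")
  n <- length(labels)
  if (is.null(channels)) channels <- substr(labels, 1, 1)
  channels <- toupper(channels)
  if (!all(channels %in% c("H", "N"))) {
    stop("unknown channel label; channels must be 'H' or 'N'")
  }
  if (is.null(couplings)) couplings <- matrix(0, n, n)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n))) {
    stop("couplings must be an n x n matrix matching the number of spins")
  }
  if (max(abs(couplings - t(couplings))) > 1e-12) {
    stop("coupling table must be symmetric (J_ij = J_ji)")
  }
  diag(couplings) <- 0
  dimnames(couplings) <- list(labels, labels)
  offsets <- rep_len(offsets, n)
  structure(
    list(labels = labels, channels = channels, couplings = couplings,
         offsets = offsets, n = n),
    class = "spin_system"
  )
}

#' Built-in SABRE spin systems
#'
#' `"threeSpin"` is the two chemically equivalent hydride protons plus one
#' equatorial 15N: J_H1H2 = -8 Hz, J_H1N1 = -22 Hz (trans), J_H2N1 = 0 (cis).
#' `"fourSpin"` adds a second 15N trans-coupled to the other hydride
#' (J_H2N2 = -22 Hz) with all cis and N-N couplings zero; it is
#' mirror-symmetric in the two hydride/nitrogen pairs.
#'
#' @param name `"threeSpin"` or `"fourSpin"`.
#' @param J_HH,J_NHt,J_NHc Scalar couplings in Hz: hydride-hydride,
#'   trans H-N, cis H-N.
#' @return A [spin_system()].
#' @export
spin_system_preset <- function(name = c("threeSpin", "fourSpin"),
                               J_HH = -8, J_NHt = -22, J_NHc = 0) {
  name <- match.arg(name)
  if (name == "threeSpin") {
    J <- matrix(0, 3, 3)
    J[1, 2] <- J[2, 1] <- J_HH
    J[1, 3] <- J[3, 1] <- J_NHt
    J[2, 3] <- J[3, 2] <- J_NHc
    spin_system(c("H1", "H2", "N1"), c("H", "H", "N"), J)
  } else {
    J <- matrix(0, 4, 4)
    J[1, 2] <- J[2, 1] <- J_HH
    J[1, 3] <- J[3, 1] <- J_NHt
    J[2, 4] <- J[4, 2] <- J_NHt
    J[2, 3] <- J[3, 2] <- J_NHc
    J[1, 4] <- J[4, 1] <- J_NHc
    spin_system(c("H1", "H2", "N1", "N2"), c("H", "H", "N", "N"), J)
  }
}

#' Convenience wrapper matching the generic construction interface
#'
#' Accepts either a preset name or explicit labels/couplings and returns a
#' validated [spin_system()].
#'
#' @param labels Preset name (`"threeSpin"`/`"fourSpin"`) or character vector
#'   of spin labels.
#' @inheritParams spin_system
#' @return A [spin_system()].
#' @export
build_spin_system <- function(labels, couplings = NULL, channels = NULL,
                              offsets = 0) {
  if (length(labels) == 1 && labels %in% c("threeSpin", "fourSpin")) {
    return(spin_system_preset(labels))
  }
  spin_system(labels, channels, couplings, offsets)
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d spins: %s\n", x$n,
              paste0(x$labels, "(", x$channels, ")", collapse = " ")))
  cat("couplings (Hz):\n")
  print(x$couplings)
  invisible(x)
}

channel_index <- function(system, channel) {
  if (is.numeric(channel)) return(as.integer(channel))
  idx <- which(system$channels == toupper(channel))
  if (length(idx) == 0) stop("no spins on channel '", channel, "'")
  idx
}
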