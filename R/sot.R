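# Simulation engine: a cached context avoids re-diagonalizing the Hamiltonian
# and rebuilding pulse propagators for every grid point of a polarization map.
sot_engine <- function(system) {
  ev <- hamiltonian_eigen(system)
  n <- system$n
  pulse_cache <- new.env(parent = emptyenv())
  delay_cache <- new.env(parent = emptyenv())
  get_pulse <- function(channel, flip, phase) {
    key <- paste(channel, flip, phase, sep = "_")
    if (is.null(pulse_cache[[key]])) {
      pulse_cache[[key]] <- pulse_propagator(
        n, channel_index(system, channel), flip, phase)
    }
    pulse_cache[[key]]
  }
  get_delay <- function(t) {
    key <- format(t, digits = 15)
    if (is.null(delay_cache[[key]])) {
      delay_cache[[key]] <- delay_propagator(ev, t)
    }
    delay_cache[[key]]
  }
  n_spins <- which(system$channels == "N")
  d <- 2^n
  nz_ops <- lapply(n_spins, function(s) spin_op(n, s, "z"))
  apply_filter <- function(rho) {
    rho_f <- diag(d) / d + 0i
    for (m in seq_along(n_spins)) {
      cj <- sum(diag(rho %*% nz_ops[[m]])) / (d / 4)
      rho_f <- rho_f + cj * nz_ops[[m]]
    }
    rho_f
  }

  run <- function(sequence, state, targets) {
    rho <- state$rho
    for (k in seq_len(nrow(sequence$events))) {
      e <- sequence$events[k, ]
      if (e$event == "pulse") {
        rho <- conjugate_rho(rho, get_pulse(e$channel, e$flip, e$phase))
      } else if (e$event == "delay") {
        if (e$duration > 0) rho <- conjugate_rho(rho, get_delay(e$duration))
      } else if (e$event == "filter") {
        # retain identity + longitudinal single-spin 15N terms
        rho <- apply_filter(rho)
      }
    }
    mean(vapply(targets, function(s) 2 * transverse_amplitude(rho, n, s),
                numeric(1)))
  }
  list(run = run, system = system, get_pulse = get_pulse,
       get_delay = get_delay, apply_filter = apply_filter)
}

#' Run a spin-order-transfer sequence and measure 15N polarization
#'
#' Propagates the initial hydride spin order (see [initial_hydride_order()])
#' through the sequence with ideal pulses and no relaxation, and returns the
#' per-15N polarization magnitude at the end of the SOT block
#' (`2 |<I+>|` averaged over the target spins). Deterministic.
#'
#' @param system A [spin_system()].
#' @param sequence A [sot_sequence()], or a sequence name (then `tau1`,
#'   `tau2` must be given).
#' @param targets Integer indices of the target spins; defaults to all
#'   N-channel spins. Must be on the N channel.
#' @param tau1,tau2 Delays in seconds, used when `sequence` is a name.
#' @param init `"zz"` or `"singlet"` initial hydride order.
#' @return Polarization as a dimensionless fraction.
#' @examples
#' sys <- spin_system_preset("threeSpin")
#' run_sot(sys, sot_sequence("phINEPT+", 0.012, 0.012))
#' @export
run_sot <- function(system, sequence, targets = NULL, tau1 = NULL,
                    tau2 = NULL, init = "zz") {
  if (is.character(sequence)) sequence <- sot_sequence(sequence, tau1, tau2)
  if (is.null(targets)) targets <- which(system$channels == "N")
  if (!all(system$channels[targets] == "N")) {
    stop("target spins must be on the N channel")
  }
  eng <- sot_engine(system)
  st <- initial_hydride_order(system, type = init)
  eng$run(sequence, st, targets)
}

# Compiled sequence program: the event list with delay slots, avoiding
# per-grid-point reconstruction of the event table.
seq_program <- function(sequence_name) {
  sq <- sot_sequence(sequence_name, 1, 2)  # marker delays 1 -> tau1, 2 -> tau2
  ev <- sq$events
  steps <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    if (ev$event[k] == "pulse") {
      steps[[k]] <- list(type = "pulse", channel = ev$channel[k],
                         flip = ev$flip[k], phase = ev$phase[k])
    } else if (ev$event[k] == "delay") {
      steps[[k]] <- list(type = "delay",
                         slot = if (ev$duration[k] == 1) "tau1" else "tau2")
    } else {
      steps[[k]] <- list(type = "filter")
    }
  }
  list(steps = steps, name = sq$name)
}

run_program <- function(eng, prog, rho, tau1, tau2, targets) {
  n <- eng$system$n
  for (st in prog$steps) {
    if (st$type == "pulse") {
      rho <- conjugate_rho(rho, eng$get_pulse(st$channel, st$flip, st$phase))
    } else if (st$type == "delay") {
      t <- if (st$slot == "tau1") tau1 else tau2
      if (t > 0) rho <- conjugate_rho(rho, eng$get_delay(t))
    } else {
      rho <- eng$apply_filter(rho)
    }
  }
  tot <- 0
  for (s in targets) tot <- tot + 2 * transverse_amplitude(rho, n, s)
  tot / length(targets)
}

#' Polarization map over the sequence delays
#'
#' Evaluates the sequence for every (tau1, tau2) grid combination and applies
#' the chemical-exchange damping factor `exp(-k_d * t_tot)`, which accounts
#' for the fraction of complexes that survive the SOT block intact.
#'
#' @param system A [spin_system()].
#' @param sequence_name `"phINEPT+"` or `"ESOTHERIC"`.
#' @param tau1_grid,tau2_grid Numeric vectors of delays in seconds.
#' @param k_d Dissociation rate constant in s^-1 (>= 0) used for damping.
#' @param init Initial hydride order, `"zz"` or `"singlet"`.
#' @return A tibble of class `sot_map` with columns `tau1_s`, `tau2_s`,
#'   `polarization` (damped, fraction) and `undamped`; attributes `sequence`
#'   and `k_d`.
#' @export
sot_map <- function(system, sequence_name, tau1_grid, tau2_grid, k_d = 0,
                    init = "zz") {
  if (length(tau1_grid) == 0 || length(tau2_grid) == 0) {
    stop("delay grids must be non-empty")
  }
  if (k_d < 0) stop("k_d must be non-negative")
  eng <- sot_engine(system)
  st <- initial_hydride_order(system, type = init)
  targets <- which(system$channels == "N")
  prog <- seq_program(sequence_name)
  grid <- tidyr::expand_grid(tau1_s = tau1_grid, tau2_s = tau2_grid)
  pol <- purrr::map2_dbl(grid$tau1_s, grid$tau2_s, function(t1, t2) {
    run_program(eng, prog, st$rho, t1, t2, targets)
  })
  seqs <- sot_sequence(sequence_name, 1, 1) # canonical name
  ttot <- purrr::map2_dbl(grid$tau1_s, grid$tau2_s,
                          function(t1, t2) sot_sequence(sequence_name, t1, t2)$t_tot)
  out <- dplyr::mutate(grid, undamped = pol,
                       polarization = pol * exp(-k_d * ttot))
  out <- out[, c("tau1_s", "tau2_s", "polarization", "undamped")]
  attr(out, "sequence") <- seqs$name
  attr(out, "k_d") <- k_d
  class(out) <- c("sot_map", class(out))
  out
}

#' Optimize the SOT delays
#'
#' Coarse grid search (default 1 ms spacing, matching the experimental map
#' resolution) followed by local Nelder-Mead refinement of the damped
#' polarization. Deterministic given the bounds and grid.
#'
#' @param system A [spin_system()].
#' @param sequence_name `"phINEPT+"` or `"ESOTHERIC"`.
#' @param bounds Length-2 numeric, lower/upper delay bound in seconds for
#'   both tau1 and tau2. Default `c(0.001, 0.040)`.
#' @param grid_step Coarse grid spacing in seconds. Default 1 ms.
#' @param k_d Damping dissociation rate constant, s^-1.
#' @param init Initial hydride order.
#' @return One-row tibble with `tau1_s`, `tau2_s`, `polarization` (damped),
#'   `undamped`, `t_tot_s`, `sequence`, `k_d`.
#' @export
optimize_sot <- function(system, sequence_name, bounds = c(0.001, 0.040),
                         grid_step = 0.001, k_d = 0, init = "zz") {
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[2] <= bounds[1]) {
    stop("bounds must be positive and increasing")
  }
  taus <- seq(bounds[1], bounds[2], by = grid_step)
  eng <- sot_engine(system)
  st <- initial_hydride_order(system, type = init)
  targets <- which(system$channels == "N")
  prog <- seq_program(sequence_name)
  esoth <- prog$name == "ESOTHERIC"
  objective <- function(par) {
    t1 <- min(max(par[1], bounds[1]), bounds[2])
    t2 <- min(max(par[2], bounds[1]), bounds[2])
    t_tot <- if (esoth) 2 * (2 * t1 + t2) else 2 * (t1 + t2)
    -run_program(eng, prog, st$rho, t1, t2, targets) * exp(-k_d * t_tot)
  }
  best <- c(NA, NA); best_val <- Inf
  for (t1 in taus) {
    for (t2 in taus) {
      v <- objective(c(t1, t2))
      if (v < best_val) { best_val <- v; best <- c(t1, t2) }
    }
  }
  opt <- stats::optim(best, objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  par <- pmin(pmax(opt$par, bounds[1]), bounds[2])
  if (opt$value > best_val) { par <- best; opt$value <- best_val }
  sq <- sot_sequence(sequence_name, par[1], par[2])
  undamped <- run_program(eng, prog, st$rho, par[1], par[2], targets)
  tibble::tibble(
    tau1_s = par[1], tau2_s = par[2],
    polarization = undamped * exp(-k_d * sq$t_tot),
    undamped = undamped, t_tot_s = sq$t_tot,
    sequence = sq$name, k_d = k_d
  )
}
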