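# Internal operator algebra for spin-1/2 product spaces.
#
# Convention: rotations are generated as exp(-i * theta * (cos(phi) Fx +
# sin(phi) Fy)) with Fx,Fy the collective channel spin operators, i.e. a 90x
# pulse takes Iz -> -Iy. The free Hamiltonian keeps the full isotropic scalar
# coupling within a channel and the secular zz part across channels.

.op_single <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = diag(c(0.5, -0.5)),
  e = diag(2) + 0i
)

# operator `axis` on spin i embedded in the n-spin space (spin 1 = leftmost
# kronecker factor)
spin_op <- function(n, i, axis) {
  m <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    m <- kronecker(m, if (k == i) .op_single[[axis]] else .op_single$e)
  }
  m
}

# free-evolution Hamiltonian in rad/s
free_hamiltonian <- function(system) {
  n <- system$n
  d <- 2^n
  H <- matrix(0i, d, d)
  for (i in seq_len(n)) {
    if (system$offsets[i] != 0) {
      H <- H + 2 * pi * system$offsets[i] * spin_op(n, i, "z")
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      J <- system$couplings[i, j]
      if (J == 0) next
      if (system$channels[i] == system$channels[j]) {
        H <- H + 2 * pi * J *
          (spin_op(n, i, "x") %*% spin_op(n, j, "x") +
           spin_op(n, i, "y") %*% spin_op(n, j, "y") +
           spin_op(n, i, "z") %*% spin_op(n, j, "z"))
      } else {
        H <- H + 2 * pi * J * (spin_op(n, i, "z") %*% spin_op(n, j, "z"))
      }
    }
  }
  H
}

# eigendecomposition cache of the (Hermitian) free Hamiltonian
hamiltonian_eigen <- function(system) {
  ev <- eigen(free_hamiltonian(system), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors)
}

delay_propagator <- function(ev, t) {
  ev$vectors %*% (exp(-1i * ev$values * t) * Conj(t(ev$vectors)))
}

# ideal collective hard pulse on the given spins: flip and phase in degrees
pulse_propagator <- function(n, spins, flip, phase) {
  th <- flip * pi / 180
  ph <- phase * pi / 180
  u <- cos(th / 2) * .op_single$e -
    1i * sin(th / 2) * (cos(ph) * 2 * .op_single$x + sin(ph) * 2 * .op_single$y)
  m <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    m <- kronecker(m, if (k %in% spins) u else .op_single$e)
  }
  m
}

conjugate_rho <- function(rho, U) U %*% rho %*% Conj(t(U))
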