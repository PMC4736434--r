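#' Cartesian and ladder operators for n coupled spins 1/2
#'
#' Builds the product-basis angular momentum operators `Ix`, `Iy`, `Iz`,
#' `Ip` (raising) and `Im` (lowering) for each of `n` spins as dense
#' complex matrices of dimension `2^n`. Spin 1 occupies the leftmost slot
#' of the Kronecker product; basis state bit 0 is alpha (m = +1/2).
#'
#' @param n number of spins (1 to 10).
#' @return A list with per-spin operator lists `$spin[[i]]` (`Ix`, `Iy`,
#'   `Iz`, `Ip`, `Im`), the total operators `$Fz`, `$Fp`, and the vector
#'   `$Mz` of total magnetic quantum numbers of the basis states.
#' @examples
#' ops <- spin_operators(2)
#' Re(sum(diag(ops$spin[[1]]$Iz %*% ops$spin[[1]]$Iz)))  # 1
#' @export
spin_operators <- function(n) {
  if (n < 1 || n > 10) stop("spin_operators supports 1 to 10 spins")
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  sz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  e2 <- diag(2)
  one_spin <- function(i, op) {
    m <- matrix(1 + 0i, 1, 1)
    for (k in seq_len(n)) {
      m <- kronecker(m, if (k == i) op else e2)
    }
    m
  }
  spins <- lapply(seq_len(n), function(i) {
    Ix <- one_spin(i, sx + 0i)
    Iy <- one_spin(i, sy)
    Iz <- one_spin(i, sz + 0i)
    list(Ix = Ix, Iy = Iy, Iz = Iz, Ip = Ix + 1i * Iy, Im = Ix - 1i * Iy)
  })
  dim_ <- 2^n
  # m value of each basis state: bit k (MSB = spin 1) 0 -> +1/2, 1 -> -1/2
  Mz <- numeric(dim_)
  for (i in seq_len(n)) Mz <- Mz + Re(diag(spins[[i]]$Iz))
  Fz <- Reduce(`+`, lapply(spins, `[[`, "Iz"))
  Fp <- Reduce(`+`, lapply(spins, `[[`, "Ip"))
  list(n = n, dim = dim_, spin = spins, Fz = Fz, Fp = Fp, Mz = Mz)
}

#' Free-evolution Hamiltonian of a spin system
#'
#' Returns the rotating-frame Hamiltonian in angular frequency units,
#' `H = 2 pi (sum_i nu_i Iiz + sum_{i<j} J_ij (Ix Ix + Iy Iy + Iz Iz))`
#' for the `"strong"` (isotropic) model, or with the coupling term
#' truncated to `J_ij Iiz Ijz` for the `"weak"` (first-order) model.
#' The eigendecomposition is computed once and stored so that propagators
#' for arbitrary delays are cheap.
#'
#' @param system a [spin_system()].
#' @param model `"strong"` (default) or `"weak"`.
#' @param ops optional precomputed [spin_operators()] set.
#' @param extra_offset_hz optional scalar offset in Hz added to every spin
#'   (used for gradient-encoded z slices).
#' @return An object of class `hamiltonian` with elements `matrix`,
#'   `values` (rad/s), `vectors`, `model`.
#' @export
free_hamiltonian <- function(system, model = c("strong", "weak"),
                             ops = NULL, extra_offset_hz = 0) {
  model <- match.arg(model)
  if (is.null(ops)) ops <- spin_operators(system$n_spins)
  nu <- offsets_hz(system) + extra_offset_hz
  H <- matrix(0i, ops$dim, ops$dim)
  for (i in seq_len(system$n_spins)) {
    H <- H + nu[i] * ops$spin[[i]]$Iz
  }
  n <- system$n_spins
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        Jij <- system$J_Hz[i, j]
        if (Jij == 0) next
        si <- ops$spin[[i]]; sj <- ops$spin[[j]]
        H <- H + if (model == "strong") {
          Jij * (si$Ix %*% sj$Ix + si$Iy %*% sj$Iy + si$Iz %*% sj$Iz)
        } else {
          Jij * (si$Iz %*% sj$Iz)
        }
      }
    }
  }
  H <- 2 * pi * H
  eig <- eigen(H, symmetric = TRUE)
  structure(list(matrix = H, values = eig$values, vectors = eig$vectors,
                 model = model),
            class = "hamiltonian")
}

#' Thermal (high-temperature) initial state
#'
#' The deviation density operator at thermal equilibrium, `sum_i Iiz`
#' (identity part dropped, Boltzmann factor normalised away).
#'
#' @inheritParams free_hamiltonian
#' @return complex matrix of dimension `2^n`.
#' @export
thermal_state <- function(system, ops = NULL) {
  if (is.null(ops)) ops <- spin_operators(system$n_spins)
  ops$Fz + 0i
}

#' Propagate a state under a Hamiltonian
#'
#' Unitary evolution `rho -> U rho U^H` with `U = exp(-i H t)`, computed
#' from the eigendecomposition stored in the [free_hamiltonian()] object.
#'
#' @param state complex density matrix.
#' @param H a `hamiltonian` (or any complex Hermitian matrix).
#' @param t time in seconds (>= 0).
#' @return evolved density matrix.
#' @export
evolve_state <- function(state, H, t) {
  if (t < 0) stop("evolution time must be non-negative")
  if (t == 0) return(state)
  U <- propagator(H, t)
  U %*% state %*% Conj(t(U))
}

# U = exp(-i H t); accepts a hamiltonian object or a raw Hermitian matrix
propagator <- function(H, t) {
  if (inherits(H, "hamiltonian")) {
    V <- H$vectors
    ph <- exp(-1i * H$values * t)
  } else {
    if (max(abs(H - Conj(t(H)))) > 1e-8 * max(1, max(abs(H)))) {
      stop("Hamiltonian must be Hermitian")
    }
    eig <- eigen(H, symmetric = TRUE)
    V <- eig$vectors
    ph <- exp(-1i * eig$values * t)
  }
  V %*% (ph * Conj(t(V)))
}

#' Ideal RF pulse on selected spins
#'
#' Exact rotation by `theta` about the transverse axis with RF phase
#' `phase` (0 = x, pi/2 = y), applied to the given spins only. All other
#' spins are untouched, which models both hard pulses (all spins) and
#' ideal frequency-selective pulses (a subset).
#'
#' @param state density matrix.
#' @param spins integer indices of the spins rotated.
#' @param theta flip angle in radians.
#' @param phase RF phase in radians.
#' @param ops [spin_operators()] set matching the state dimension.
#' @return rotated density matrix.
#' @export
apply_pulse <- function(state, spins, theta, phase = 0, ops) {
  U <- pulse_unitary(ops, spins, theta, phase)
  U %*% state %*% Conj(t(U))
}

# Kronecker-factorised pulse propagator (exact for ideal pulses)
pulse_unitary <- function(ops, spins, theta, phase = 0) {
  n <- ops$n
  c2 <- cos(theta / 2)
  s2 <- sin(theta / 2)
  # single-spin rotation about (cos phase, sin phase, 0):
  # exp(-i theta (Ix cos phase + Iy sin phase))
  r <- matrix(c(c2, -1i * s2 * exp(-1i * phase),
                -1i * s2 * exp(1i * phase), c2), 2, 2, byrow = TRUE)
  U <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    U <- kronecker(U, if (k %in% spins) r else diag(2) + 0i)
  }
  U
}

#' Keep only chosen coherence orders
#'
#' Software surrogate for pulsed-field-gradient selection: matrix elements
#' of the state whose total coherence order (difference of total magnetic
#' quantum numbers of the connected basis states) is not in `orders` are
#' zeroed. Idempotent.
#'
#' @param state density matrix.
#' @param orders integer vector of coherence orders to keep.
#' @param ops matching [spin_operators()] set.
#' @return filtered density matrix.
#' @export
coherence_filter <- function(state, orders, ops) {
  if (length(orders) == 0) {
    warning("empty coherence-order set: state zeroed")
    return(state * 0)
  }
  state * coherence_mask(ops, orders)
}

# logical mask of elements with total coherence order in `orders`
coherence_mask <- function(ops, orders) {
  P <- outer(ops$Mz, ops$Mz, `-`)
  (matrix(round(P) %in% round(orders), ops$dim, ops$dim)) + 0
}

#' Quadrature detection
#'
#' Returns the complex signal `Tr(rho sum_i Ii+)`, scaled so that a unit
#' in-phase transverse term (`rho = Iix`) detects as exactly 1. With this
#' convention the detected coherence order is -1 and a positive resonance
#' offset produces a positive-frequency signal.
#'
#' @param state density matrix.
#' @param ops matching [spin_operators()] set.
#' @param spins spins to include (default all).
#' @return complex scalar (or vector if `per_spin = TRUE`).
#' @param per_spin return one amplitude per detected spin.
#' @export
detect_signal <- function(state, ops, spins = seq_len(ops$n),
                          per_spin = FALSE) {
  scale <- 4 / ops$dim
  vals <- vapply(spins, function(i) {
    sum(state * t(ops$spin[[i]]$Ip)) * scale
  }, complex(1))
  if (per_spin) vals else sum(vals)
}

#' Apply transverse relaxation to a detected signal
#'
#' Multiplies a complex time-domain signal by the phenomenological
#' envelope `exp(-t / T2)`, giving Lorentzian lines of full width at half
#' maximum `1 / (pi T2)` after Fourier transformation. `T2 = Inf` leaves
#' the signal unchanged.
#'
#' @param signal complex vector.
#' @param t_axis times in seconds, same length as `signal`.
#' @param T2_s transverse relaxation time in seconds.
#' @return damped complex vector.
#' @export
apply_t2_decay <- function(signal, t_axis, T2_s) {
  if (length(signal) != length(t_axis)) {
    stop("signal and t_axis lengths differ")
  }
  if (is.infinite(T2_s)) return(signal)
  signal * exp(-t_axis / T2_s)
}
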