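#' PSYCHE element parameters
#'
#' Settings for the low-flip-angle double-chirp (saltire) element that
#' performs the statistical active-spin selection at the heart of the
#' experiment. In `"ideal"` mode the element is modelled by its net
#' effect: for each spin k in turn, the single-quantum coherence of k is
#' inverted (an exact 180 degree rotation of k alone), the longitudinal
#' states of all other spins are preserved, and all cross-transfer terms
#' are discarded, with uniform amplitude across spins. In `"explicit"`
#' mode two simultaneous counter-sweeping frequency chirps of net flip
#' angle `beta_deg` are propagated as a piecewise-constant RF Hamiltonian
#' on a grid of z positions whose gradient-encoded offsets span
#' `gradient_encoding_Hz`, and the slice results are averaged.
#'
#' @param mode `"ideal"` or `"explicit"`.
#' @param beta_deg net flip angle of each chirp in degrees (0, 45].
#' @param duration_s chirp duration in seconds.
#' @param sweep_Hz chirp frequency sweep width in Hz.
#' @param n_time_slices piecewise-constant discretisation of the chirps.
#' @param n_z_slices number of z positions in the spatial average.
#' @param gradient_encoding_Hz full spread of gradient-induced offsets
#'   across the sample during the element.
#' @return An object of class `psyche_params`.
#' @export
psyche_params <- function(mode = c("ideal", "explicit"), beta_deg = 15,
                          duration_s = 0.030, sweep_Hz = 10000,
                          n_time_slices = 1000, n_z_slices = 50,
                          gradient_encoding_Hz = sweep_Hz) {
  mode <- match.arg(mode)
  if (beta_deg <= 0 || beta_deg > 45) {
    stop("beta_deg must lie in (0, 45]")
  }
  structure(list(mode = mode, beta_deg = beta_deg, duration_s = duration_s,
                 sweep_Hz = sweep_Hz, n_time_slices = n_time_slices,
                 n_z_slices = n_z_slices,
                 gradient_encoding_Hz = gradient_encoding_Hz),
            class = "psyche_params")
}

# mask keeping elements where spin k is the only "open" (transverse) spin
single_spin_sq_mask <- function(ops, k) {
  dim_ <- ops$dim
  n <- ops$n
  idx <- 0:(dim_ - 1)
  r <- rep(idx, times = dim_)
  c <- rep(idx, each = dim_)
  differ <- bitwXor(r, c)
  keep <- differ == bitwShiftL(1L, n - k)
  matrix(as.numeric(keep), dim_, dim_)
}

#' Apply the PSYCHE element to a density state
#'
#' Both modes conserve the coherence-order-reversing branch selected by
#' the coherence-transfer-pathway gradients that flank the element: the
#' input is decomposed into its p = +1 and p = -1 single-quantum blocks,
#' each block is sent through the element, and only the order-reversed
#' component of each result is kept (software equivalent of the matched
#' gradient pair).
#'
#' @param state density matrix (or, in explicit mode, optionally a list of
#'   per-z-slice states that are propagated slice by slice and returned as
#'   a list without the spatial average).
#' @param psyche a [psyche_params()].
#' @param system the [spin_system()].
#' @param ops matching [spin_operators()] set.
#' @param phase RF phase of the element in radians (phase-cycled).
#' @param propagators optional precomputed [psyche_propagators()] result
#'   (explicit mode; built on the fly if missing).
#' @return density matrix (or list of per-slice matrices).
#' @export
apply_psyche <- function(state, psyche, system, ops, phase = 0,
                         propagators = NULL) {
  if (psyche$mode == "ideal") {
    if (is.list(state) && !is.matrix(state)) {
      stop("ideal mode takes a single state")
    }
    return(psyche_ideal(state, ops, phase))
  }
  if (is.null(propagators)) {
    propagators <- psyche_propagators(psyche, system, ops, phase = phase)
  }
  if (is.list(state) && !is.matrix(state)) {
    if (length(state) != length(propagators$U)) {
      stop("one state per z slice expected")
    }
    return(mapply(function(s, U) U %*% s %*% Conj(t(U)),
                  state, propagators$U, SIMPLIFY = FALSE))
  }
  out <- 0
  for (p in c(1, -1)) {
    block <- coherence_filter(state, p, ops)
    acc <- 0
    for (U in propagators$U) {
      acc <- acc + U %*% block %*% Conj(t(U))
    }
    acc <- acc / length(propagators$U)
    out <- out + coherence_filter(acc, -p, ops)
  }
  out
}

# ideal active-spin projection: sum over k of (180 on k) applied to the
# part of rho where only spin k is transverse and all others are diagonal
psyche_ideal <- function(state, ops, phase = 0) {
  out <- matrix(0i, ops$dim, ops$dim)
  for (k in seq_len(ops$n)) {
    mask <- psyche_mask_cache(ops, k)
    blk <- state * mask
    U <- pulse_unitary(ops, k, pi, phase)
    out <- out + U %*% blk %*% Conj(t(U))
  }
  out
}

# per-process cache of the single-spin SQ masks (keyed by n and k)
.psyche_masks <- new.env(parent = emptyenv())
psyche_mask_cache <- function(ops, k) {
  key <- paste0(ops$n, ".", k)
  m <- .psyche_masks[[key]]
  if (is.null(m)) {
    m <- single_spin_sq_mask(ops, k)
    .psyche_masks[[key]] <- m
  }
  m
}

#' Piecewise-constant propagators of the explicit saltire element
#'
#' Builds one unitary per z slice for the double-chirp element: the free
#' Hamiltonian of the system plus the gradient offset of the slice plus
#' the RF field of two simultaneous chirps sweeping `-sweep/2 -> +sweep/2`
#' and `+sweep/2 -> -sweep/2`, each calibrated (by simulating a single
#' chirp on a lone on-resonance spin) to a net flip angle `beta_deg`.
#'
#' @inheritParams apply_psyche
#' @return list with `U` (list of per-slice unitaries), `omega1_rad`
#'   (calibrated RF amplitude) and `z_offsets_hz`.
#' @export
psyche_propagators <- function(psyche, system, ops, phase = 0) {
  stopifnot(psyche$mode == "explicit")
  nts <- psyche$n_time_slices
  tau <- psyche$duration_s
  bw <- psyche$sweep_Hz
  dt <- tau / nts
  tt <- (seq_len(nts) - 0.5) * dt
  omega1 <- calibrate_chirp_amplitude(psyche)
  # instantaneous phases of the two counter-sweeping chirps
  ph_up <- 2 * pi * (-bw / 2 * tt + bw / (2 * tau) * tt^2) + phase
  ph_dn <- 2 * pi * (+bw / 2 * tt - bw / (2 * tau) * tt^2) + phase
  wx <- omega1 * (cos(ph_up) + cos(ph_dn))
  wy <- omega1 * (sin(ph_up) + sin(ph_dn))
  nz <- psyche$n_z_slices
  z_off <- if (nz == 1) 0 else
    psyche$gradient_encoding_Hz * ((seq_len(nz) - 1) / (nz - 1) - 0.5)
  Fx <- Reduce(`+`, lapply(ops$spin, `[[`, "Ix"))
  Fy <- Reduce(`+`, lapply(ops$spin, `[[`, "Iy"))
  H0 <- free_hamiltonian(system, "strong", ops)$matrix
  Us <- lapply(z_off, function(dz) {
    Hz <- H0 + 2 * pi * dz * ops$Fz
    U <- diag(ops$dim) + 0i
    for (k in seq_len(nts)) {
      Hk <- Hz + wx[k] * Fx + wy[k] * Fy
      eig <- eigen(Hk, symmetric = TRUE)
      Uk <- eig$vectors %*% (exp(-1i * eig$values * dt) *
                               Conj(t(eig$vectors)))
      U <- Uk %*% U
    }
    U
  })
  list(U = Us, omega1_rad = omega1, z_offsets_hz = z_off)
}

# RF amplitude giving a net on-resonance flip of beta for ONE chirp,
# found by root-finding on a single-spin simulation seeded with the
# Landau-Zener small-flip estimate.
calibrate_chirp_amplitude <- function(psyche) {
  beta <- psyche$beta_deg * pi / 180
  nts <- psyche$n_time_slices
  tau <- psyche$duration_s
  bw <- psyche$sweep_Hz
  dt <- tau / nts
  tt <- (seq_len(nts) - 0.5) * dt
  ph <- 2 * pi * (-bw / 2 * tt + bw / (2 * tau) * tt^2)
  flip_of <- function(w1) {
    # closed-form 2x2 rotations, state tracked as Bloch vector
    v <- c(0, 0, 1)
    for (k in seq_len(nts)) {
      # on-resonance spin: effective field is the chirp RF alone, whose
      # phase sweeps through the stationary point at mid-pulse
      ax <- c(w1 * cos(ph[k]), w1 * sin(ph[k]), 0)
      ang <- sqrt(sum(ax^2)) * dt
      if (ang > 0) {
        u <- ax / sqrt(sum(ax^2))
        v <- v * cos(ang) + pracma_cross(u, v) * sin(ang) +
          u * sum(u * v) * (1 - cos(ang))
      }
    }
    acos(max(-1, min(1, v[3]))) - beta
  }
  rate <- 2 * pi * bw / tau
  p_target <- sin(beta / 2)^2
  w_guess <- sqrt(-2 * rate * log(1 - p_target) / pi)
  lo <- w_guess / 4
  hi <- w_guess * 4
  # widen until bracketed (flip grows monotonically at small amplitudes)
  f_lo <- flip_of(lo); f_hi <- flip_of(hi)
  tries <- 0
  while (f_lo * f_hi > 0 && tries < 8) {
    lo <- lo / 2; hi <- hi * 2
    f_lo <- flip_of(lo); f_hi <- flip_of(hi)
    tries <- tries + 1
  }
  stats::uniroot(flip_of, c(lo, hi), tol = 1e-6)$root
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
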