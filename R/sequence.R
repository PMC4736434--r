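#' Acquisition parameters for the selective pure shift 2DJ experiment
#'
#' Collects every knob of the pulse sequence and of the pseudo-3D
#' acquisition: the selection band for the selective 180 degree pulses,
#' the three time dimensions (t1: selective J evolution; t2: pure shift
#' increments; t3: directly acquired chunks), the PSYCHE element
#' settings, the acquisition type and the phase-cycling strategy.
#'
#' The chunk of data acquired per t2 increment has duration
#' `1/SW2_Hz = points_per_chunk / SW_acq_Hz`; `points_per_chunk` must
#' therefore equal `SW_acq_Hz / SW2_Hz` exactly. With
#' `chunk_mode = "half_first"` (the interferogram convention used by
#' default) the first increment contributes only its first half chunk
#' and later increments are centred on the t2 sampling grid.
#'
#' @param selected_band either `c(center_ppm, width_ppm)` describing the
#'   band covered by the selective pulses, or a list
#'   `list(spins = c(...))` naming spin indices directly.
#' @param n1,SW1_Hz t1 increments and F1 spectral width (Hz).
#' @param n2,SW2_Hz t2 increments and F2 pure shift width (Hz).
#' @param points_per_chunk complex points acquired per chunk.
#' @param SW_acq_Hz t3 sampling rate (Hz).
#' @param acquisition_type `"both"`, `"N"` or `"R"`.
#' @param psyche a [psyche_params()].
#' @param phase_cycle `"ctp_filter_shortcut"` (single transient with
#'   gradient-surrogate pathway selection) or `"full"` (the 32-step cycle
#'   Phi1 = 0x4 2x4, Phi2 = 0x8 2x8, Phi3 = 0123, Phi4 = 0x16 2x16,
#'   receiver = -Phi1 + 2 Phi3).
#' @param noise_sigma standard deviation of the additive complex Gaussian
#'   noise per point (0 = noiseless).
#' @param seed integer seed for the noise generator.
#' @param chunk_mode `"half_first"` or `"aligned"`.
#' @param model Hamiltonian model used by the simulator, `"strong"`
#'   (isotropic, default) or `"weak"` (first-order secular).
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(selected_band, n1 = 64, SW1_Hz = 50,
                            n2 = 16, SW2_Hz = 50, points_per_chunk = 40,
                            SW_acq_Hz = 2000,
                            acquisition_type = c("both", "N", "R"),
                            psyche = psyche_params(),
                            phase_cycle = c("ctp_filter_shortcut", "full"),
                            noise_sigma = 0, seed = 1,
                            chunk_mode = c("half_first", "aligned"),
                            model = c("strong", "weak")) {
  acquisition_type <- match.arg(acquisition_type)
  phase_cycle <- match.arg(phase_cycle)
  chunk_mode <- match.arg(chunk_mode)
  model <- match.arg(model)
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be >= 1")
  if (abs(points_per_chunk - SW_acq_Hz / SW2_Hz) > 1e-9) {
    stop("points_per_chunk must equal SW_acq_Hz / SW2_Hz ",
         "(chunk duration 1/SW2)")
  }
  if (chunk_mode == "half_first" && points_per_chunk %% 2 != 0) {
    stop("half_first chunk mode needs an even points_per_chunk")
  }
  structure(list(selected_band = selected_band, n1 = n1, SW1_Hz = SW1_Hz,
                 n2 = n2, SW2_Hz = SW2_Hz,
                 points_per_chunk = points_per_chunk,
                 SW_acq_Hz = SW_acq_Hz,
                 acquisition_type = acquisition_type, psyche = psyche,
                 phase_cycle = phase_cycle, noise_sigma = noise_sigma,
                 seed = seed, chunk_mode = chunk_mode, model = model),
            class = "sequence_params")
}

#' Spins covered by the selection band
#'
#' @param system a [spin_system()].
#' @param band `c(center_ppm, width_ppm)` or `list(spins = indices)`.
#' @return integer vector of selected spin indices (possibly empty, with
#'   a warning: the experiment then degenerates to a pure shift spectrum
#'   with no active couplings).
#' @export
select_spins <- function(system, band) {
  if (is.list(band) && !is.null(band$spins)) {
    sel <- sort(unique(as.integer(band$spins)))
    if (any(sel < 1 | sel > system$n_spins)) stop("spin index out of range")
    return(sel)
  }
  if (length(band) != 2 || band[2] <= 0) {
    stop("band must be c(center_ppm, width_ppm) with positive width")
  }
  sel <- which(abs(system$shift_ppm - band[1]) <= band[2] / 2)
  if (length(sel) == 0) {
    warning("selection band contains no spins; no couplings will be active")
  }
  sel
}

#' Apply an ideal selective 180 degree pulse
#'
#' Exact pi rotation of the selected spins about the axis `phase`;
#' unselected spins are untouched.
#'
#' @param state density matrix.
#' @param selected integer spin indices.
#' @param ops matching [spin_operators()].
#' @param phase RF phase in radians.
#' @return rotated density matrix.
#' @export
apply_selective_180 <- function(state, selected, ops, phase = 0) {
  if (length(selected) == 0) return(state)
  apply_pulse(state, selected, pi, phase, ops)
}

# phases (in 90-degree units) of the 32-step cycle; receiver = -P1 + 2 P3
phase_cycle_table <- function() {
  s <- 0:31
  data.frame(p1 = 2 * ((s %/% 4) %% 2),
             p2 = 2 * ((s %/% 8) %% 2),
             p3 = s %% 4,
             p4 = 2 * ((s %/% 16) %% 2),
             pr = (-2 * ((s %/% 4) %% 2) + 2 * (s %% 4)) %% 4)
}

# t2 delay grid implied by the chunking convention
t2_grid <- function(params) {
  j <- seq_len(params$n2) - 1
  if (params$chunk_mode == "half_first") {
    ifelse(j == 0, 0, (j - 0.5) / params$SW2_Hz)
  } else {
    j / params$SW2_Hz
  }
}

#' Run the selective pure shift 2DJ pulse sequence
#'
#' Full density-matrix simulation of the N- and/or R-type experiment.
#' The sequence is
#' `90(Phi1) - SEL - BIP(Phi2) - t2/2 - PSYCHE(Phi3) - BIP(Phi4) - SEL -
#' t2/2 - acquire`, with the two t1/2 evolution halves placed after the
#' two selective pulses for the N-type experiment and before them for the
#' R-type; the two placements differ only in the sense of the selective
#' J evolution. The net effect, enforced by the analytic oracle tests, is
#' that during t1 only couplings to the selected spins evolve, during t2
#' the chemical shift plus the selected couplings evolve, and during each
#' acquired chunk (t3) the full Hamiltonian is active.
#'
#' Coherence pathway selection uses an exact software surrogate of the
#' gradient scheme (the order-reversing branch through the PSYCHE element
#' is kept); the 32-step phase cycle can be summed explicitly with
#' `phase_cycle = "full"`.
#'
#' @param system a [spin_system()].
#' @param params a [sequence_params()].
#' @return A `raw_dataset`: complex array `data[type, t1, t2, t3]` plus
#'   axes and metadata.
#' @export
run_psychedelic <- function(system, params) {
  ops <- spin_operators(system$n_spins)
  selected <- select_spins(system, params$selected_band)
  if (length(selected)) {
    jsel <- abs(system$J_Hz[selected, , drop = FALSE])
    if (max(jsel) > params$SW1_Hz) {
      warning("SW1 is smaller than the largest selected coupling; ",
              "F1 doublets will fold")
    }
  }
  if (params$psyche$mode == "explicit" &&
      params$psyche$sweep_Hz / params$psyche$n_time_slices >
      params$SW_acq_Hz) {
    warning("PSYCHE time discretisation is coarse: frequency step per ",
            "slice exceeds the acquisition bandwidth")
  }
  eng <- sequence_engine(system, params, ops, selected)
  types <- switch(params$acquisition_type, both = c("N", "R"),
                  N = "N", R = "R")
  t1g <- (seq_len(params$n1) - 1) / params$SW1_Hz
  t2g <- t2_grid(params)
  ppc <- params$points_per_chunk
  dat <- array(0i, c(length(types), params$n1, params$n2, ppc))
  cyc <- if (params$phase_cycle == "full") phase_cycle_table() else
    data.frame(p1 = 0, p2 = 0, p3 = 0, p4 = 0, pr = 0)
  for (it in seq_along(types)) {
    for (j in seq_len(params$n2)) {
      for (i in seq_len(params$n1)) {
        acc <- complex(ppc)
        for (s in seq_len(nrow(cyc))) {
          sg <- eng$transient(types[it], t1g[i], t2g[j],
                              c(cyc$p1[s], cyc$p2[s], cyc$p3[s], cyc$p4[s]))
          acc <- acc + sg * exp(-1i * pi / 2 * cyc$pr[s])
        }
        dat[it, i, j, ] <- acc / nrow(cyc)
      }
    }
  }
  if (params$noise_sigma > 0) {
    set.seed(as.integer(params$seed))
    nn <- length(dat)
    dat <- dat + params$noise_sigma *
      complex(real = stats::rnorm(nn), imaginary = stats::rnorm(nn))
  }
  structure(list(data = dat, types = types, t1 = t1g, t2 = t2g,
                 t3 = (seq_len(ppc) - 1) / params$SW_acq_Hz,
                 params = params, system = system, selected = selected),
            class = "raw_dataset")
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf(
    "<raw_dataset> types {%s}  n1=%d  n2=%d  points/chunk=%d  (%s)\n",
    paste(x$types, collapse = ","), length(x$t1), length(x$t2),
    length(x$t3), x$params$phase_cycle))
  cat(sprintf("  selected spins: %s\n",
              if (length(x$selected))
                paste(x$system$labels[x$selected], collapse = ", ")
              else "none"))
  invisible(x)
}

# Precomputes everything reused across increments and returns a closure
# that simulates one transient.
sequence_engine <- function(system, params, ops, selected) {
  H <- free_hamiltonian(system, params$model, ops)
  V <- H$vectors
  Vh <- Conj(t(V))
  lam <- H$values
  N <- ops$dim
  ppc <- params$points_per_chunk
  t3 <- (seq_len(ppc) - 1) / params$SW_acq_Hz
  # detection: s_i(t3) = sum_rs (Vh rho V)_rs (Vh Ii+ V)_sr e^{-i w_rs t3}
  E3 <- exp(-1i * outer(as.vector(outer(lam, lam, `-`)), t3))
  scale <- 4 / N
  Bt <- lapply(ops$spin, function(sp) t(Vh %*% sp$Ip %*% V) * scale)
  env3 <- lapply(system$T2_s, function(T2) exp(-t3 / T2))
  rho_eq <- thermal_state(system, ops)
  # 90 pulse with base axis y so a zero-phase transient detects in
  # absorption; cycled in 90-degree steps
  rho0 <- lapply(0:3, function(p) {
    U <- pulse_unitary(ops, seq_len(ops$n), pi / 2, pi / 2 + p * pi / 2)
    U %*% rho_eq %*% Conj(t(U))
  })
  Usel <- if (length(selected)) {
    pulse_unitary(ops, selected, pi, 0)
  } else NULL
  Ubip <- lapply(0:3, function(p) {
    pulse_unitary(ops, seq_len(ops$n), pi, p * pi / 2)
  })
  delay_cache <- new.env(parent = emptyenv())
  Udelay <- function(t) {
    key <- format(t, digits = 15)
    u <- delay_cache[[key]]
    if (is.null(u)) {
      u <- V %*% (exp(-1i * lam * t) * Vh)
      delay_cache[[key]] <- u
    }
    u
  }
  psy_cache <- new.env(parent = emptyenv())
  psy_apply <- function(rho, p3) {
    if (params$psyche$mode == "ideal") {
      return(psyche_ideal(rho, ops, p3 * pi / 2))
    }
    key <- as.character(p3)
    pr <- psy_cache[[key]]
    if (is.null(pr)) {
      pr <- psyche_propagators(params$psyche, system, ops,
                               phase = p3 * pi / 2)
      psy_cache[[key]] <- pr
    }
    apply_psyche(rho, params$psyche, system, ops, phase = p3 * pi / 2,
                 propagators = pr)
  }
  sandwich <- function(rho, U) U %*% rho %*% Conj(t(U))
  transient <- function(type, t1, t2, phases) {
    U1 <- Udelay(t1 / 2)
    U2 <- Udelay(t2 / 2)
    rho <- rho0[[phases[1] + 1]]
    if (type == "R") rho <- sandwich(rho, U1)
    if (!is.null(Usel)) rho <- sandwich(rho, Usel)
    if (type == "N") rho <- sandwich(rho, U1)
    rho <- sandwich(rho, Ubip[[phases[2] + 1]])
    rho <- sandwich(rho, U2)
    rho <- psy_apply(rho, phases[3])
    rho <- sandwich(rho, Ubip[[phases[4] + 1]])
    if (type == "R") rho <- sandwich(rho, U1)
    if (!is.null(Usel)) rho <- sandwich(rho, Usel)
    if (type == "N") rho <- sandwich(rho, U1)
    rho <- sandwich(rho, U2)
    A <- Vh %*% rho %*% V
    sig <- complex(ppc)
    for (i in seq_len(ops$n)) {
      w <- as.vector(A * Bt[[i]])
      si <- drop(matrix(w, 1) %*% E3)
      sig <- sig + si * env3[[i]] * exp(-(t1 + t2) / system$T2_s[i])
    }
    sig
  }
  list(transient = transient, H = H, ops = ops)
}

#' Closed-form weak-coupling signal model (oracle)
#'
#' Analytic prediction of the raw data for weakly coupled systems,
#' independent of the density-matrix engine. For each spin k the signal
#' is a sum over the 2^(n-1) z-states of its partners: couplings to
#' selected spins modulate t1 at +/- pi J (conjugated in the R-type
#' experiment), t2 carries the chemical shift plus the selected
#' couplings, and t3 the shift plus all couplings, with the per-spin T2
#' envelope over the total evolution time. A selected spin's own signal
#' instead modulates t1 with its shift plus its non-selected couplings
#' (which are also what survives in its t2), matching the pathway its
#' magnetization takes through the two selective pulses.
#'
#' @inheritParams run_psychedelic
#' @return A `raw_dataset` with the same shape as [run_psychedelic()].
#' @export
analytic_signal <- function(system, params) {
  ops_n <- system$n_spins
  selected <- select_spins(system, params$selected_band)
  types <- switch(params$acquisition_type, both = c("N", "R"),
                  N = "N", R = "R")
  t1g <- (seq_len(params$n1) - 1) / params$SW1_Hz
  t2g <- t2_grid(params)
  ppc <- params$points_per_chunk
  t3 <- (seq_len(ppc) - 1) / params$SW_acq_Hz
  nu <- offsets_hz(system)
  dat <- array(0i, c(length(types), params$n1, params$n2, ppc))
  amp <- 2^(1 - ops_n)
  for (k in seq_len(ops_n)) {
    others <- setdiff(seq_len(ops_n), k)
    sel_partners <- intersect(others, selected)
    own_selected <- k %in% selected
    # enumerate z states of all other spins
    cfg <- if (length(others) == 0) matrix(numeric(0), 1, 0) else
      as.matrix(expand.grid(rep(list(c(0.5, -0.5)), length(others))))
    for (r in seq_len(nrow(cfg))) {
      m <- cfg[r, ]
      Ball <- sum(system$J_Hz[k, others] * 2 * m)          # all couplings
      Bsel <- if (length(sel_partners))
        sum(system$J_Hz[k, sel_partners] * 2 *
              m[match(sel_partners, others)]) else 0
      Buns <- Ball - Bsel
      if (own_selected) {
        w1 <- 2 * pi * nu[k] + pi * Buns
        w2 <- pi * Buns
      } else {
        w1 <- pi * Bsel
        w2 <- 2 * pi * nu[k] + pi * Bsel
      }
      w3 <- 2 * pi * nu[k] + pi * Ball
      f3 <- exp(1i * w3 * t3 - t3 / system$T2_s[k])
      for (it in seq_along(types)) {
        sgn <- if (types[it] == "N") 1 else -1
        f1 <- exp((1i * sgn * w1 - 1 / system$T2_s[k]) * t1g)
        f2 <- exp((1i * w2 - 1 / system$T2_s[k]) * t2g)
        dat[it, , , ] <- as.vector(dat[it, , , ]) +
          amp * as.vector(outer(f1, outer(f2, f3)))
      }
    }
  }
  structure(list(data = dat, types = types, t1 = t1g, t2 = t2g, t3 = t3,
                 params = params, system = system, selected = selected),
            class = "raw_dataset")
}

#' Reduced one-dimensional acquisition modes
#'
#' `"t1_only"` increments only t1 and acquires a single full-length FID
#' per increment (no chunking): an absorption-mode, non-pure-shift 2DJ
#' experiment with selective coupling evolution. `"t2_only"` increments
#' only t2 with chunked acquisition: a 1D pure shift spectrum in which
#' only the selected couplings are reintroduced.
#'
#' In both modes `points_per_chunk` of `params` is reinterpreted as the
#' total number of points acquired per increment where appropriate.
#'
#' @inheritParams run_psychedelic
#' @param mode `"t1_only"` or `"t2_only"`.
#' @return A `raw_dataset`.
#' @export
run_reduced <- function(system, params, mode = c("t1_only", "t2_only")) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "t1_only") {
    p$n2 <- 1L
    p$SW2_Hz <- p$SW_acq_Hz / p$points_per_chunk  # one chunk = whole FID
    p$chunk_mode <- "aligned"
  } else {
    p$n1 <- 1L
  }
  out <- run_psychedelic(system, p)
  out$reduced_mode <- mode
  out
}
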