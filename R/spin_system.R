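#' Define a scalar-coupled spin system
#'
#' A `spin_system` holds everything the simulator needs to know about the
#' molecule side of the experiment: chemical shifts in ppm, the proton
#' Larmor frequency used to convert ppm to Hz, the rotating-frame carrier
#' position, the symmetric matrix of scalar couplings in Hz, and per-spin
#' transverse relaxation times.
#'
#' The resonance offset of spin i in the rotating frame is
#' `(shift_ppm[i] - carrier_ppm) * spectrometer_MHz` Hz.
#'
#' @param shift_ppm numeric vector of chemical shifts (ppm), one per spin.
#' @param J_Hz symmetric numeric matrix of scalar couplings in Hz with zero
#'   diagonal. A scalar 0 is accepted for a single spin.
#' @param spectrometer_MHz proton Larmor frequency in MHz (ppm-to-Hz factor).
#' @param carrier_ppm rotating-frame reference position; defaults to the
#'   mean chemical shift.
#' @param T2_s per-spin transverse relaxation time in seconds (recycled).
#' @param labels optional per-spin names.
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(c(4.2, 4.6), matrix(c(0, 7, 7, 0), 2),
#'                    spectrometer_MHz = 500, carrier_ppm = 4.0)
#' offsets_hz(sys)
#' @export
spin_system <- function(shift_ppm, J_Hz, spectrometer_MHz = 500,
                        carrier_ppm = mean(shift_ppm), T2_s = 1,
                        labels = NULL) {
  n <- length(shift_ppm)
  if (n < 1L) stop("spin system needs at least one spin")
  if (n == 1L && (is.null(dim(J_Hz)) && all(J_Hz == 0))) {
    J_Hz <- matrix(0, 1, 1)
  }
  J_Hz <- as.matrix(J_Hz)
  if (!all(dim(J_Hz) == c(n, n))) {
    stop("J_Hz must be an n x n matrix (n = ", n, ")")
  }
  if (max(abs(J_Hz - t(J_Hz))) > 1e-9) {
    stop("J matrix must be symmetric")
  }
  if (any(abs(diag(J_Hz)) > 0)) stop("J matrix must have zero diagonal")
  T2_s <- rep_len(as.numeric(T2_s), n)
  if (any(!is.finite(T2_s) & !is.infinite(T2_s)) || any(T2_s <= 0)) {
    stop("all T2 values must be positive")
  }
  if (is.null(labels)) labels <- paste0("H", seq_len(n))
  if (length(labels) != n) stop("labels length must match number of spins")
  structure(
    list(n_spins = n,
         shift_ppm = as.numeric(shift_ppm),
         spectrometer_MHz = as.numeric(spectrometer_MHz),
         carrier_ppm = as.numeric(carrier_ppm),
         J_Hz = unname(J_Hz),
         T2_s = T2_s,
         labels = as.character(labels)),
    class = "spin_system")
}

#' Rotating-frame offsets in Hz
#'
#' @param system a [spin_system()].
#' @return numeric vector of per-spin offsets from the carrier, in Hz.
#' @export
offsets_hz <- function(system) {
  (system$shift_ppm - system$carrier_ppm) * system$spectrometer_MHz
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d spins at %.1f MHz (carrier %.3f ppm)\n",
              x$n_spins, x$spectrometer_MHz, x$carrier_ppm))
  off <- offsets_hz(x)
  for (i in seq_len(x$n_spins)) {
    partners <- which(x$J_Hz[i, ] != 0)
    jtxt <- if (length(partners)) {
      paste(sprintf("%s:%.2f", x$labels[partners], x$J_Hz[i, partners]),
            collapse = " ")
    } else "-"
    cat(sprintf("  %-6s %7.3f ppm (%+9.2f Hz)  T2 %.2f s  J{%s}\n",
                x$labels[i], x$shift_ppm[i], off[i], x$T2_s[i], jtxt))
  }
  invisible(x)
}

#' Canned spin-system fixtures
#'
#' Small invented spin systems used throughout the test-suite and the demo.
#' They are test inputs, not literature parameter sets.
#'
#' \describe{
#'   \item{AX}{two weakly coupled spins at offsets 100 and 300 Hz, J = 7 Hz.}
#'   \item{AMX}{three weakly coupled spins.}
#'   \item{AB}{two strongly coupled spins, offset difference 10 Hz = J.}
#'   \item{residue4}{HN / Halpha / Hbeta2 / Hbeta3 of a peptide-like residue,
#'     J(Halpha, .) = 8 / 5 / 11 Hz plus a 12 Hz geminal coupling.}
#'   \item{ring6}{six crowded ring protons with vicinal/geminal couplings
#'     in the 3-13 Hz range and adjacent shift spacings below 0.2 ppm.}
#'   \item{alpha_family}{two residue fragments whose Halpha shifts fall in
#'     one selection band, plus an alkene-like proton coupled to both
#'     Halpha spins (the doublet-of-doublets case).}
#' }
#'
#' @param name one of `"AX"`, `"AMX"`, `"AB"`, `"residue4"`, `"ring6"`,
#'   `"alpha_family"`.
#' @return A [spin_system()].
#' @examples
#' canned_system("AX")$J_Hz[1, 2]  # 7
#' @export
canned_system <- function(name) {
  switch(
    name,
    AX = spin_system(c(4.2, 4.6), jmat(2, c(1, 2, 7)),
                     spectrometer_MHz = 500, carrier_ppm = 4.0,
                     T2_s = 1.5, labels = c("A", "X")),
    AMX = spin_system(c(3.6, 4.06, 4.5),
                      jmat(3, c(1, 2, 7), c(1, 3, 3), c(2, 3, 11)),
                      spectrometer_MHz = 500, carrier_ppm = 4.0,
                      T2_s = 1.5, labels = c("A", "M", "X")),
    AB = spin_system(c(2.0, 2.02), jmat(2, c(1, 2, 10)),
                     spectrometer_MHz = 500, carrier_ppm = 2.01,
                     T2_s = 2, labels = c("A", "B")),
    residue4 = spin_system(
      c(8.3, 4.4, 2.7, 2.2),
      jmat(4, c(1, 2, 8), c(2, 3, 5), c(2, 4, 11), c(3, 4, 12)),
      spectrometer_MHz = 500, carrier_ppm = 4.4, T2_s = 1,
      labels = c("HN", "Ha", "Hb2", "Hb3")),
    ring6 = spin_system(
      c(3.20, 3.35, 3.50, 3.62, 3.78, 3.90),
      jmat(6, c(1, 2, 9.5), c(2, 3, 3.5), c(3, 4, 10.2),
           c(4, 5, 5.5), c(5, 6, 8.1), c(1, 6, 13)),
      spectrometer_MHz = 500, carrier_ppm = 3.55, T2_s = 1,
      labels = paste0("R", 1:6)),
    alpha_family = spin_system(
      c(4.20, 4.50, 5.80, 8.20, 1.90),
      jmat(5, c(1, 3, 9.5), c(2, 3, 4.0), c(1, 4, 8.0), c(2, 5, 6.5)),
      spectrometer_MHz = 500, carrier_ppm = 4.9, T2_s = 1,
      labels = c("Ha1", "Ha2", "Hx", "HN1", "Hb2")),
    stop("unknown canned system: ", name)
  )
}

# build a symmetric J matrix from (i, j, value) triples
jmat <- function(n, ...) {
  J <- matrix(0, n, n)
  for (tr in list(...)) {
    J[tr[1], tr[2]] <- tr[3]
    J[tr[2], tr[1]] <- tr[3]
  }
  J
}

#' Seeded random spin systems
#'
#' Draws a random weakly (or arbitrarily) coupled spin system. Shifts are
#' uniform over a window of `shift_span_hz` around the carrier with a
#' minimum pairwise separation (so that peaks remain resolvable at the
#' digital resolutions used in the pipeline), couplings are sparse-random
#' in `j_range`, and with `weak_only = TRUE` every coupled pair is
#' guaranteed an offset-difference-to-J ratio of at least `min_ratio`.
#'
#' @param seed integer seed; the same seed always returns the same system.
#' @param n_spins number of spins (<= 8).
#' @param shift_span_hz full width of the shift window in Hz.
#' @param j_range range of coupling magnitudes in Hz.
#' @param j_density probability that a given spin pair is coupled.
#' @param weak_only enforce `min |offset difference| / J >= min_ratio` for
#'   all coupled pairs.
#' @param min_ratio weak-coupling floor on offset/J ratios.
#' @param min_sep_hz minimum pairwise shift separation in Hz.
#' @param t2_range range of per-spin T2 values in seconds.
#' @param spectrometer_MHz Larmor frequency.
#' @param max_tries retry budget before giving up.
#' @return A [spin_system()].
#' @export
random_system <- function(seed, n_spins = 4, shift_span_hz = 2000,
                          j_range = c(2, 15), j_density = 0.6,
                          weak_only = TRUE, min_ratio = 20,
                          min_sep_hz = 60, t2_range = c(0.5, 2),
                          spectrometer_MHz = 500, max_tries = 500) {
  if (n_spins > 8) stop("random_system supports at most 8 spins")
  set.seed(as.integer(seed))
  carrier <- 4.0
  for (try in seq_len(max_tries)) {
    off <- sort(stats::runif(n_spins, -shift_span_hz / 2, shift_span_hz / 2))
    if (n_spins > 1 && min(diff(off)) < min_sep_hz) next
    J <- matrix(0, n_spins, n_spins)
    npair <- n_spins * (n_spins - 1) / 2
    ok <- TRUE
    for (i in seq_len(n_spins - 1)) {
      for (j in seq(i + 1, n_spins)) {
        if (stats::runif(1) < j_density) {
          jmax <- j_range[2]
          if (weak_only) jmax <- min(jmax, abs(off[i] - off[j]) / min_ratio)
          # a pair too close to support any weak coupling stays uncoupled
          if (jmax >= j_range[1]) {
            J[i, j] <- J[j, i] <- stats::runif(1, j_range[1], jmax)
          }
        }
      }
    }
    # require at least one coupling so the fixture exercises J evolution
    if (n_spins > 1 && all(J == 0)) ok <- FALSE
    if (!ok) next
    T2 <- stats::runif(n_spins, t2_range[1], t2_range[2])
    return(spin_system(carrier + off / spectrometer_MHz, J,
                       spectrometer_MHz = spectrometer_MHz,
                       carrier_ppm = carrier, T2_s = T2))
  }
  stop("random_system: could not satisfy constraints in ", max_tries,
       " tries")
}
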