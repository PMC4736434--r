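#' Concatenate acquired chunks into pure shift FIDs
#'
#' Each t2 increment contributes a chunk of duration `1/SW2` acquired in
#' t3. Because the sequence parks the accumulated phase at the chunk
#' start at `shift + selected couplings` while the full Hamiltonian runs
#' within the chunk, concatenating the chunks yields an effectively
#' homodecoupled t2' FID; the residual within-chunk modulation by
#' unselected couplings is what produces the decoupling sidebands at
#' multiples of SW2. With the `"half_first"` convention the first
#' increment contributes only its first half chunk and later increments
#' are centred on the t2' grid, which minimises those sidebands.
#'
#' @param raw a `raw_dataset` from [run_psychedelic()] or
#'   [analytic_signal()].
#' @return A `pure_shift_td` object: complex array `data[type, t1, t2']`
#'   plus axes.
#' @export
assemble_chunks <- function(raw) {
  p <- raw$params
  ppc <- p$points_per_chunk
  if (abs(ppc / p$SW_acq_Hz - 1 / p$SW2_Hz) > 1e-9) {
    stop("chunk duration (points_per_chunk / SW_acq) must equal 1/SW2")
  }
  n2 <- p$n2
  half <- p$chunk_mode == "half_first" && n2 > 1
  L <- if (half) ppc / 2 + (n2 - 1) * ppc else n2 * ppc
  ntype <- length(raw$types)
  n1 <- length(raw$t1)
  out <- array(0i, c(ntype, n1, L))
  for (it in seq_len(ntype)) {
    for (i in seq_len(n1)) {
      pos <- 1
      for (j in seq_len(n2)) {
        take <- if (half && j == 1) seq_len(ppc / 2) else seq_len(ppc)
        out[it, i, pos:(pos + length(take) - 1)] <- raw$data[it, i, j, take]
        pos <- pos + length(take)
      }
    }
  }
  structure(list(data = out, types = raw$types, t1 = raw$t1,
                 dwell = 1 / p$SW_acq_Hz, SW1_Hz = p$SW1_Hz,
                 params = p, system = raw$system, selected = raw$selected),
            class = "pure_shift_td")
}

#' Echo/antiecho recombination of N- and R-type data
#'
#' Combines the normal and reversed t1-evolution datasets in the classic
#' echo/antiecho manner: `cos = (S_N + S_R)/2`,
#' `sin = (S_N - S_R)/(2i)`. After the two Fourier transforms the
#' real/real quadrant then contains pure double-absorption peaks instead
#' of the phasetwist lineshapes of a phase-modulated 2DJ experiment.
#'
#' @param ps a `pure_shift_td` containing both N and R blocks.
#' @return A `pk_data` object with `cos` and `sin` arrays `[t1, t2']`.
#' @export
pk_recombine <- function(ps) {
  iN <- match("N", ps$types)
  iR <- match("R", ps$types)
  if (is.na(iN) || is.na(iR)) {
    stop("echo/antiecho recombination needs both N and R blocks")
  }
  SN <- ps$data[iN, , , drop = FALSE]
  SR <- ps$data[iR, , , drop = FALSE]
  dim(SN) <- dim(SN)[-1]; dim(SR) <- dim(SR)[-1]
  structure(list(cos = (SN + SR) / 2, sin = (SN - SR) / (2i),
                 t1 = ps$t1, dwell = ps$dwell, SW1_Hz = ps$SW1_Hz,
                 params = ps$params, system = ps$system,
                 selected = ps$selected),
            class = "pk_data")
}

fftshift_idx <- function(M) {
  s <- ceiling(M / 2)
  c((s + 1):M, 1:s)
}

shifted_freqs <- function(M, sw) {
  df <- sw / M
  (seq_len(M) - 1 - (M - ceiling(M / 2))) * df
}

# apodize + zero-fill + FT + shift one row (complex time -> complex freq)
ft_row <- function(x, window, zf_len) {
  x <- x * window
  x[1] <- x[1] * 0.5
  x <- c(x, complex(zf_len - length(x)))
  stats::fft(x)[fftshift_idx(zf_len)]
}

#' Two-dimensional Fourier transform to an absorption-mode 2DJ spectrum
#'
#' States-style processing: the t2' dimension of the cosine- and
#' sine-modulated datasets is apodized (exponential line broadening,
#' default matched to the mean T2 of the system), zero-filled and
#' transformed; after zero-order phasing the real parts are combined
#' into a complex t1 interferogram, apodized with a decaying cosine,
#' zero-filled and transformed. The real/real quadrant is stored as the
#' spectrum intensity; all four quadrants are kept for lineshape
#' diagnostics. A single-type (`pure_shift_td`) input is transformed as
#' phase-modulated data instead (the classic phasetwist route).
#'
#' @param x a `pk_data` (absorption route) or `pure_shift_td` (N-only
#'   route; the first stored type is used).
#' @param zero_fill zero-filling factor for both dimensions.
#' @param lb2_hz exponential line broadening in t2' (Hz); default
#'   `1/(pi * mean(T2))` of the simulated system, 1 Hz if unknown.
#' @param phase0 zero-order phase correction applied in F2, radians.
#' @return A `spectrum2d`.
#' @export
ft2d <- function(x, zero_fill = 2, lb2_hz = NULL, phase0 = 0) {
  pk <- inherits(x, "pk_data")
  if (!pk && !inherits(x, "pure_shift_td")) {
    stop("ft2d expects pk_data or pure_shift_td input")
  }
  if (is.null(lb2_hz)) {
    lb2_hz <- if (!is.null(x$system)) 1 / (pi * mean(x$system$T2_s)) else 1
  }
  if (pk) {
    cosd <- x$cos; sind <- x$sin
  } else {
    d <- x$data[1, , , drop = FALSE]
    dim(d) <- dim(d)[-1]
    cosd <- d; sind <- NULL
  }
  if (is.null(dim(cosd))) cosd <- matrix(cosd, nrow = 1)
  n1 <- nrow(cosd)
  L <- ncol(cosd)
  sw2 <- 1 / x$dwell
  t2ax <- (seq_len(L) - 1) * x$dwell
  w2 <- exp(-pi * lb2_hz * t2ax)
  M2 <- zero_fill * L
  F2cos <- t(apply(cosd, 1, ft_row, window = w2, zf_len = M2))
  if (n1 == 1) F2cos <- matrix(F2cos, nrow = 1)
  ph <- exp(-1i * phase0)
  F2cos <- F2cos * ph
  if (pk) {
    sind <- if (is.null(dim(sind))) matrix(sind, nrow = 1) else sind
    F2sin <- t(apply(sind, 1, ft_row, window = w2, zf_len = M2))
    if (n1 == 1) F2sin <- matrix(F2sin, nrow = 1)
    F2sin <- F2sin * ph
  }
  f2_hz <- shifted_freqs(M2, sw2)
  sys <- x$system
  f2_ppm <- if (!is.null(sys)) {
    sys$carrier_ppm + f2_hz / sys$spectrometer_MHz
  } else f2_hz
  if (n1 > 1) {
    w1 <- cos(pi * (seq_len(n1) - 1) / (2 * n1))
    M1 <- zero_fill * n1
    if (pk) {
      c1 <- Re(F2cos) + 1i * Re(F2sin)
      c2 <- Im(F2cos) + 1i * Im(F2sin)
    } else {
      c1 <- F2cos
      c2 <- -1i * F2cos
    }
    S1 <- apply(c1, 2, ft_row, window = w1, zf_len = M1)
    S2 <- apply(c2, 2, ft_row, window = w1, zf_len = M1)
    quad <- list(RR = Re(S1), IR = Im(S1), RI = Re(S2), II = Im(S2))
    f1_hz <- shifted_freqs(M1, x$SW1_Hz)
  } else {
    quad <- list(RR = matrix(Re(F2cos), 1), IR = matrix(0, 1, M2),
                 RI = matrix(Im(F2cos), 1), II = matrix(0, 1, M2))
    f1_hz <- 0
  }
  structure(list(intensity = quad$RR, quadrants = quad,
                 f1_hz = f1_hz, f2_hz = f2_hz, f2_ppm = f2_ppm,
                 phase0 = phase0, lb2_hz = lb2_hz, tilt = FALSE,
                 mode = if (pk) "pk" else "n_only",
                 system = sys, selected = x$selected,
                 log = c(sprintf("ft2d zero_fill=%d lb2=%.3fHz phase0=%.3f",
                                 zero_fill, lb2_hz, phase0))),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf(
    "<spectrum2d> %d x %d (%s)%s  F1 %.1f..%.1f Hz  F2 %.2f..%.2f ppm\n",
    nrow(x$intensity), ncol(x$intensity), x$mode,
    if (x$tilt) " tilted" else "", min(x$f1_hz), max(x$f1_hz),
    min(x$f2_ppm), max(x$f2_ppm)))
  invisible(x)
}

# circular sub-bin shift of a real vector by `bins` via Fourier phase ramp
fourier_shift <- function(y, bins) {
  M <- length(y)
  k <- c(0:(ceiling(M / 2) - 1), -(M - ceiling(M / 2)):-1)
  ramp <- exp(2i * pi * k * bins / M)
  if (M %% 2 == 0) ramp[M / 2 + 1] <- cos(2 * pi * k[M / 2 + 1] * bins / M)
  Re(stats::fft(stats::fft(y) * ramp, inverse = TRUE)) / M
}

#' 45 degree tilt (shear) of a 2DJ spectrum
#'
#' Relocates intensity from (f1, f2) to (f1, f2 - f1): each F1 row is
#' shifted along F2 by its own F1 frequency with a sub-bin-accurate
#' Fourier-domain phase ramp. In a J-resolved spectrum the doublet
#' components lie on -45 degree diagonals, so the shear moves the active
#' couplings entirely into F1, leaving pure chemical shifts in F2.
#'
#' @param spec an untilted `spectrum2d`.
#' @return the sheared `spectrum2d` with the tilt flag set.
#' @export
tilt45 <- function(spec) {
  if (spec$tilt) stop("spectrum is already tilted")
  df2 <- spec$f2_hz[2] - spec$f2_hz[1]
  for (q in names(spec$quadrants)) {
    m <- spec$quadrants[[q]]
    for (i in seq_along(spec$f1_hz)) {
      m[i, ] <- fourier_shift(m[i, ], spec$f1_hz[i] / df2)
    }
    spec$quadrants[[q]] <- m
  }
  spec$intensity <- spec$quadrants$RR
  spec$tilt <- TRUE
  spec$log <- c(spec$log, "tilt45 (f1, f2) -> (f1, f2 - f1)")
  spec
}

#' Extract an F1 trace at a given F2 position
#'
#' Returns the F1 column of a tilted spectrum at the requested F2
#' position, linearly interpolated between the two neighbouring columns.
#'
#' @param spec a tilted `spectrum2d`.
#' @param f2_ppm position in ppm (or give `f2_hz`).
#' @param f2_hz position in Hz relative to the carrier.
#' @return list with `f1_hz` and `intensity`.
#' @export
f1_trace <- function(spec, f2_ppm = NULL, f2_hz = NULL) {
  if (!spec$tilt) stop("f1_trace needs a tilted spectrum")
  if (is.null(f2_hz)) {
    if (is.null(f2_ppm)) stop("give f2_ppm or f2_hz")
    sys <- spec$system
    f2_hz <- if (!is.null(sys)) {
      (f2_ppm - sys$carrier_ppm) * sys$spectrometer_MHz
    } else f2_ppm
  }
  ax <- spec$f2_hz
  if (f2_hz < min(ax) || f2_hz > max(ax)) {
    stop("requested F2 position is outside the spectrum")
  }
  j <- findInterval(f2_hz, ax)
  j <- min(max(j, 1), length(ax) - 1)
  w <- (f2_hz - ax[j]) / (ax[j + 1] - ax[j])
  y <- (1 - w) * spec$intensity[, j] + w * spec$intensity[, j + 1]
  list(f1_hz = spec$f1_hz, intensity = y)
}

#' Full width at half maximum of a peak
#'
#' Measures the FWHM of the tallest peak of a 1D trace by linear
#' interpolation of the half-height crossings.
#'
#' @param freq frequency axis.
#' @param y intensity.
#' @return width in the units of `freq`.
#' @export
measure_fwhm <- function(freq, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  il <- i0
  while (il > 1 && y[il] > half) il <- il - 1
  ir <- i0
  while (ir < length(y) && y[ir] > half) ir <- ir + 1
  if (il == i0 || ir == i0) return(NA_real_)
  xl <- freq[il] + (half - y[il]) / (y[il + 1] - y[il]) *
    (freq[il + 1] - freq[il])
  xr <- freq[ir - 1] + (half - y[ir - 1]) / (y[ir] - y[ir - 1]) *
    (freq[ir] - freq[ir - 1])
  xr - xl
}

#' Dispersive-to-absorptive power ratio of the strongest peak
#'
#' Lineshape diagnostic for phasetwist. The 2D region around the tallest
#' peak is resampled (separable spline) onto a grid symmetric about the
#' sub-bin-refined peak centre and decomposed into parts even and odd in
#' the two frequency offsets. A double-absorption peak `A1(d1) A2(d2)`
#' is purely even-even; a phasetwist peak `A1 A2 - D1 D2` carries the
#' dispersive cross term in the odd-odd component, whose integrated
#' power is comparable to the absorptive part. The metric is the
#' odd-odd / even-even power ratio: close to 0 for absorption
#' lineshapes, of order 1 for phasetwist.
#'
#' @param spec a `spectrum2d`.
#' @param halfwidth_bins half window (in digital points per axis) used
#'   around the peak.
#' @return dispersive/absorptive power ratio.
#' @export
phasetwist_ratio <- function(spec, halfwidth_bins = c(10, 12)) {
  m <- spec$intensity
  if (nrow(m) < 5) stop("phasetwist_ratio needs a 2D spectrum")
  halfwidth_bins <- rep_len(halfwidth_bins, 2)
  ij <- arrayInd(which.max(abs(m)), dim(m))
  # sub-bin apex refinement in both dimensions
  c1 <- refine_center(m[, ij[2]], ij[1])
  c2 <- refine_center(m[ij[1], ], ij[2])
  g1 <- sym_grid(c1, halfwidth_bins[1], nrow(m))
  g2 <- sym_grid(c2, halfwidth_bins[2], ncol(m))
  if (is.null(g1) || is.null(g2)) return(NA_real_)
  # separable spline resampling onto the symmetric grid
  tmp <- t(apply(m, 1, function(row)
    stats::spline(seq_len(ncol(m)), row, xout = g2)$y))
  g <- apply(tmp, 2, function(col)
    stats::spline(seq_len(nrow(m)), col, xout = g1)$y)
  rg1 <- g[rev(seq_len(nrow(g))), , drop = FALSE]
  rg2 <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  rgb <- rg1[, rev(seq_len(ncol(g))), drop = FALSE]
  ee <- (g + rg1 + rg2 + rgb) / 4
  oo <- (g - rg1 - rg2 + rgb) / 4
  sum(oo^2) / sum(ee^2)
}

refine_center <- function(y, i0) {
  i0 <- min(max(i0, 2), length(y) - 1)
  i0 + parabolic_delta(y[i0 - 1], y[i0], y[i0 + 1])
}

# grid of 2w+1 points centred on ctr, NULL if it does not fit the axis
sym_grid <- function(ctr, w, n) {
  g <- ctr + seq(-w, w)
  if (min(g) < 1 || max(g) > n) {
    w <- floor(min(ctr - 1, n - ctr))
    if (w < 2) return(NULL)
    g <- ctr + seq(-w, w)
  }
  g
}

#' Simulate and process in one call
#'
#' Convenience wrapper: runs the pulse sequence, assembles the chunks,
#' recombines N/R (or keeps a single type), Fourier transforms and
#' optionally tilts.
#'
#' @inheritParams run_psychedelic
#' @param tilt apply [tilt45()].
#' @param mode `"pk"` (absorption, default) or `"n_only"`.
#' @param raw optionally reuse an existing `raw_dataset`.
#' @param ... passed to [ft2d()].
#' @return a `spectrum2d`.
#' @export
psychedelic_spectrum <- function(system = NULL, params = NULL,
                                 tilt = TRUE, mode = c("pk", "n_only"),
                                 raw = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(raw)) raw <- run_psychedelic(system, params)
  ps <- assemble_chunks(raw)
  spec <- if (mode == "pk") ft2d(pk_recombine(ps), ...) else ft2d(ps, ...)
  if (tilt) spec <- tilt45(spec)
  spec
}

#' Fraction of spectral power away from expected peak positions
#'
#' Diagnostic for strong-coupling artifacts: sums the squared intensity
#' of the spectrum outside rectangular windows centred on the expected
#' first-order peak positions and divides by the total power. Weakly
#' coupled systems processed through the pipeline concentrate
#' essentially all power inside the windows; strong coupling among
#' detected spins pushes intensity to non-first-order positions.
#'
#' @param spec a `spectrum2d`.
#' @param expected data.frame with columns `f1_hz`, `f2_hz` of expected
#'   peak positions.
#' @param win_f1_hz,win_f2_hz half widths of the exclusion windows.
#' @return fraction in `[0, 1]`.
#' @export
offpattern_fraction <- function(spec, expected, win_f1_hz = 3,
                                win_f2_hz = 8) {
  m <- spec$intensity^2
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(expected))) {
    i1 <- abs(spec$f1_hz - expected$f1_hz[r]) <= win_f1_hz
    i2 <- abs(spec$f2_hz - expected$f2_hz[r]) <= win_f2_hz
    keep[i1, i2] <- TRUE
  }
  sum(m[!keep]) / sum(m)
}
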