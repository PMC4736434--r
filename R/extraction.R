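#' Locate peaks along F2
#'
#' Local maxima of the F1-integrated positive skyline of a tilted
#' spectrum, above a relative threshold, with sub-bin positions from
#' three-point parabolic interpolation.
#'
#' @param spec a tilted `spectrum2d`.
#' @param threshold fraction of the tallest skyline point below which
#'   maxima are ignored.
#' @return data.frame with `f2_hz`, `f2_ppm`, `height`; empty (with a
#'   warning) if nothing rises above the threshold.
#' @export
pick_f2_peaks <- function(spec, threshold = 0.1) {
  if (!spec$tilt) stop("pick_f2_peaks needs a tilted spectrum")
  sky <- colSums(pmax(spec$intensity, 0))
  if (max(sky) <= 0) {
    warning("no peaks found")
    return(data.frame(f2_hz = numeric(0), f2_ppm = numeric(0),
                      height = numeric(0)))
  }
  thr <- threshold * max(sky)
  n <- length(sky)
  idx <- which(sky > thr &
                 sky >= c(-Inf, sky[-n]) & sky > c(sky[-1], -Inf))
  idx <- idx[idx > 1 & idx < n]
  if (length(idx) == 0) {
    warning("no peaks found")
    return(data.frame(f2_hz = numeric(0), f2_ppm = numeric(0),
                      height = numeric(0)))
  }
  df2 <- spec$f2_hz[2] - spec$f2_hz[1]
  pos <- vapply(idx, function(i) {
    spec$f2_hz[i] + parabolic_delta(sky[i - 1], sky[i], sky[i + 1]) * df2
  }, numeric(1))
  sys <- spec$system
  ppm <- if (!is.null(sys)) {
    sys$carrier_ppm + pos / sys$spectrometer_MHz
  } else pos
  data.frame(f2_hz = pos, f2_ppm = ppm, height = sky[idx])
}

# apex offset (in bins, clamped to +/- 0.5) of a 3-point parabola
parabolic_delta <- function(a, b, c) {
  denom <- a - 2 * b + c
  if (abs(denom) < .Machine$double.eps) return(0)
  max(min(0.5 * (a - c) / denom, 0.5), -0.5)
}

#' Classify an F1 multiplet and measure its splittings
#'
#' Finds the lines of an F1 trace (local maxima above a relative height,
#' positions refined by parabolic interpolation on the log intensity,
#' which is exact around a Lorentzian apex) and matches them against the
#' patterns produced by the experiment: a singlet at 0, a doublet at
#' +/- J/2, or the four lines `+/-(J1 + J2)/2, +/-(J1 - J2)/2` of a
#' doublet of doublets (collapsing to a triplet-like three-line pattern
#' when J1 and J2 are equal within the digital resolution). Symmetric
#' pair matching about F1 = 0 is enforced; anything else is labelled
#' `"complex"` and no coupling is reported.
#'
#' @param trace list with `f1_hz` and `intensity` (from [f1_trace()]).
#' @param min_separation_hz lines closer to 0 than half this count as a
#'   singlet.
#' @param rel_height relative height cutoff for line picking.
#' @return list with `multiplicity` (`"s"`, `"d"`, `"dd"`, `"complex"`,
#'   `"empty"`), `J_hz` (numeric, largest first), `lines_hz`.
#' @export
classify_f1_multiplet <- function(trace, min_separation_hz = 1,
                                  rel_height = 0.2) {
  y <- trace$intensity
  f <- trace$f1_hz
  n <- length(y)
  if (max(y) <= 0) {
    return(list(multiplicity = "empty", J_hz = numeric(0),
                lines_hz = numeric(0)))
  }
  thr <- rel_height * max(y)
  idx <- which(y > thr & y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  idx <- idx[idx > 1 & idx < n]
  df1 <- f[2] - f[1]
  lines <- sort(vapply(idx, function(i) {
    tri <- y[(i - 1):(i + 1)]
    d <- if (all(tri > 0)) parabolic_delta(log(tri[1]), log(tri[2]),
                                           log(tri[3]))
    else parabolic_delta(tri[1], tri[2], tri[3])
    f[i] + d * df1
  }, numeric(1)))
  tol <- max(2 * df1, 0.2)
  res <- function(mult, J = numeric(0)) {
    list(multiplicity = mult, J_hz = J, lines_hz = lines)
  }
  if (length(lines) == 0) return(res("empty"))
  if (length(lines) == 1) {
    if (abs(lines) < min_separation_hz / 2) return(res("s"))
    return(res("complex"))
  }
  if (length(lines) == 2) {
    if (abs(lines[1] + lines[2]) < tol) {
      return(res("d", lines[2] - lines[1]))
    }
    return(res("complex"))
  }
  if (length(lines) == 3) {
    if (abs(lines[2]) < tol && abs(lines[1] + lines[3]) < tol) {
      a <- (lines[3] - lines[1]) / 2
      return(res("dd", c(a, a)))  # degenerate J1 = J2 ("t-like")
    }
    return(res("complex"))
  }
  if (length(lines) == 4) {
    if (abs(lines[1] + lines[4]) < tol && abs(lines[2] + lines[3]) < tol) {
      a <- (lines[4] - lines[1]) / 2
      b <- (lines[3] - lines[2]) / 2
      return(res("dd", c(a + b, a - b)))
    }
    return(res("complex"))
  }
  res("complex")
}

#' Extract every measurable coupling from a processed spectrum
#'
#' Walks the F2 peaks of a tilted, absorption-mode spectrum, classifies
#' the F1 multiplet at each position and reports the splittings. Peaks
#' at the F2 positions of the selected spins themselves are flagged
#' (`selected = TRUE`) and not J-analysed. The uncertainty reported for
#' each splitting is half the F1 digital resolution.
#'
#' @param spec a tilted `spectrum2d` (the processing metadata must be
#'   present; untilted input is an error).
#' @param threshold passed to [pick_f2_peaks()].
#' @param min_separation_hz,rel_height passed to
#'   [classify_f1_multiplet()].
#' @return a `coupling_table` (data.frame): one row per F2 peak with
#'   `f2_ppm`, `f2_hz`, `label`, `multiplicity`, `J1_hz`, `J2_hz`,
#'   `uncertainty_hz`, `selected`.
#' @export
extract_couplings <- function(spec, threshold = 0.1,
                              min_separation_hz = 1, rel_height = 0.2) {
  if (!spec$tilt) stop("extract_couplings needs a tilted spectrum")
  peaks <- pick_f2_peaks(spec, threshold)
  df1 <- if (length(spec$f1_hz) > 1) spec$f1_hz[2] - spec$f1_hz[1] else NA
  sys <- spec$system
  sel_hz <- if (!is.null(sys) && length(spec$selected)) {
    (sys$shift_ppm[spec$selected] - sys$carrier_ppm) * sys$spectrometer_MHz
  } else numeric(0)
  df2 <- spec$f2_hz[2] - spec$f2_hz[1]
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    fhz <- peaks$f2_hz[i]
    is_sel <- length(sel_hz) > 0 && min(abs(sel_hz - fhz)) < max(2 * df2, 2)
    label <- NA_character_
    if (!is.null(sys)) {
      shifts_hz <- (sys$shift_ppm - sys$carrier_ppm) * sys$spectrometer_MHz
      j <- which.min(abs(shifts_hz - fhz))
      if (abs(shifts_hz[j] - fhz) < max(2 * df2, 2)) label <- sys$labels[j]
    }
    if (is_sel) {
      return(data.frame(f2_ppm = peaks$f2_ppm[i], f2_hz = fhz,
                        label = label, multiplicity = "selected",
                        J1_hz = NA_real_, J2_hz = NA_real_,
                        uncertainty_hz = NA_real_, selected = TRUE))
    }
    cls <- classify_f1_multiplet(f1_trace(spec, f2_hz = fhz),
                                 min_separation_hz, rel_height)
    data.frame(f2_ppm = peaks$f2_ppm[i], f2_hz = fhz, label = label,
               multiplicity = cls$multiplicity,
               J1_hz = if (length(cls$J_hz) >= 1) cls$J_hz[1] else NA_real_,
               J2_hz = if (length(cls$J_hz) >= 2) cls$J_hz[2] else NA_real_,
               uncertainty_hz = df1 / 2, selected = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(f2_ppm = numeric(0), f2_hz = numeric(0),
                      label = character(0), multiplicity = character(0),
                      J1_hz = numeric(0), J2_hz = numeric(0),
                      uncertainty_hz = numeric(0), selected = logical(0))
  }
  class(out) <- c("coupling_table", "data.frame")
  attr(out, "selected_spins") <- spec$selected
  out
}

#' @export
print.coupling_table <- function(x, ...) {
  cat(sprintf("<coupling_table> %d F2 peaks\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
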