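# Minimal NMRPipe-format 2D support: a 512-float32 header followed by
# FDSPECNUM rows of FDSIZE float32 intensities. Only the header words the
# package itself needs are populated (sizes, spectral widths, observe
# frequencies, carriers, axis origins, quadrature/transform flags); a JSON
# sidecar carries everything NMRPipe has no slot for (tilt flag, processing
# log, system snapshot, exact axes).

FD <- list(MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
           F2QUADFLAG = 56L, F1QUADFLAG = 55L, SIZE = 99L, SPECNUM = 219L,
           QUADFLAG = 106L, F2SW = 100L, F2ORIG = 101L, F2OBS = 119L,
           F2CAR = 66L, F2FTFLAG = 220L, F1SW = 229L, F1ORIG = 249L,
           F1OBS = 218L, F1CAR = 67L, F1FTFLAG = 222L, TRANSPOSED = 221L,
           PHASE2D = 256L)

#' Write a processed spectrum as an NMRPipe-format file
#'
#' Writes the real 2D intensity matrix as a single NMRPipe-format binary
#' file (little-endian float32, 512-word header) with calibrated F1/F2
#' axes, plus a JSON sidecar `<path>.json` holding the tilt flag, the
#' processing log and a snapshot of the spin system, which have no
#' NMRPipe header slot. Only the documented subset of header words is
#' populated.
#'
#' @param spec a `spectrum2d`.
#' @param path output file (conventionally `.ft2`).
#' @return `path`, invisibly.
#' @export
write_spectrum_nmrpipe <- function(spec, path) {
  if (is.null(spec$f1_hz) || is.null(spec$f2_hz)) {
    stop("spectrum axes are not set")
  }
  hdr <- numeric(512)
  set <- function(i, v) hdr[i + 1] <<- v
  set(FD$MAGIC, 0)
  set(FD$FLTORDER, 2.345)
  set(FD$DIMCOUNT, 2)
  n2 <- ncol(spec$intensity); n1 <- nrow(spec$intensity)
  sys <- spec$system
  obs <- if (!is.null(sys)) sys$spectrometer_MHz else 1
  car2 <- if (!is.null(sys)) sys$carrier_ppm else 0
  set(FD$SIZE, n2)
  set(FD$SPECNUM, n1)
  set(FD$QUADFLAG, 1)         # real data
  set(FD$F2QUADFLAG, 1); set(FD$F1QUADFLAG, 1)
  set(FD$F2FTFLAG, 1); set(FD$F1FTFLAG, 1)
  set(FD$TRANSPOSED, 0)
  set(FD$PHASE2D, 2)          # States-type
  sw2 <- diff(range(spec$f2_hz)) + (spec$f2_hz[2] - spec$f2_hz[1])
  set(FD$F2SW, sw2)
  set(FD$F2OBS, obs)
  set(FD$F2CAR, car2)
  set(FD$F2ORIG, spec$f2_hz[1])
  sw1 <- if (n1 > 1) {
    diff(range(spec$f1_hz)) + (spec$f1_hz[2] - spec$f1_hz[1])
  } else 1
  set(FD$F1SW, sw1)
  set(FD$F1OBS, obs)
  set(FD$F1CAR, 0)
  set(FD$F1ORIG, spec$f1_hz[1])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4, endian = "little")
  # NMRPipe FLTFORMAT word holds the byte pattern 0xEEEEEEEE
  seek(con, 4); writeBin(as.raw(rep(0xee, 4)), con); seek(con, 512 * 4)
  writeBin(as.numeric(t(spec$intensity)), con, size = 4, endian = "little")
  sidecar <- list(tilt = spec$tilt, mode = spec$mode, phase0 = spec$phase0,
                  log = spec$log, selected = spec$selected,
                  f1_hz = spec$f1_hz, f2_hz = spec$f2_hz,
                  system = if (!is.null(sys)) list(
                    spectrometer_MHz = sys$spectrometer_MHz,
                    carrier_ppm = sys$carrier_ppm,
                    shift_ppm = sys$shift_ppm, T2_s = sys$T2_s,
                    labels = sys$labels,
                    J_Hz = sys$J_Hz) else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back an NMRPipe-format spectrum written by this package
#'
#' @param path file written by [write_spectrum_nmrpipe()].
#' @return a `spectrum2d` (quadrants other than the stored real/real
#'   intensity are not recoverable from the file).
#' @export
read_spectrum_nmrpipe <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, numeric(), 512, size = 4, endian = "little")
  get <- function(i) hdr[i + 1]
  if (abs(get(FD$FLTORDER) - 2.345) > 1e-4) {
    stop("not an NMRPipe-format file written by this machine's byte order")
  }
  n2 <- as.integer(round(get(FD$SIZE)))
  n1 <- as.integer(round(get(FD$SPECNUM)))
  dat <- readBin(con, numeric(), n1 * n2, size = 4, endian = "little")
  intensity <- matrix(dat, n1, n2, byrow = TRUE)
  sidefile <- paste0(path, ".json")
  side <- if (file.exists(sidefile)) {
    jsonlite::fromJSON(sidefile, simplifyVector = TRUE)
  } else NULL
  f2_hz <- if (!is.null(side$f2_hz)) side$f2_hz else
    get(FD$F2ORIG) + (seq_len(n2) - 1) * get(FD$F2SW) / n2
  f1_hz <- if (!is.null(side$f1_hz)) side$f1_hz else
    get(FD$F1ORIG) + (seq_len(n1) - 1) * get(FD$F1SW) / n1
  sys <- NULL
  if (!is.null(side$system)) {
    s <- side$system
    sys <- spin_system(s$shift_ppm,
                       matrix(unlist(s$J_Hz), length(s$shift_ppm)),
                       spectrometer_MHz = s$spectrometer_MHz,
                       carrier_ppm = s$carrier_ppm, T2_s = s$T2_s,
                       labels = s$labels)
  }
  f2_ppm <- if (!is.null(sys)) {
    sys$carrier_ppm + f2_hz / sys$spectrometer_MHz
  } else f2_hz
  structure(list(intensity = intensity,
                 quadrants = list(RR = intensity),
                 f1_hz = f1_hz, f2_hz = f2_hz, f2_ppm = f2_ppm,
                 phase0 = if (!is.null(side$phase0)) side$phase0 else 0,
                 tilt = isTRUE(side$tilt),
                 mode = if (!is.null(side$mode)) side$mode else "pk",
                 system = sys,
                 selected = if (!is.null(side$selected))
                   as.integer(side$selected) else integer(0),
                 log = side$log),
            class = "spectrum2d")
}
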