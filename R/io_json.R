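#' Read a spin system from JSON
#'
#' Schema:
#' \preformatted{
#' {"spectrometer_MHz": 500, "carrier_ppm": 4.0,
#'  "spins": [{"label": "A", "shift_ppm": 4.2, "T2_s": 1.5}, ...],
#'  "J_Hz": [[0, 7], [7, 0]]}
#' }
#' A missing per-spin `T2_s` defaults to 1.0 s with a warning; an
#' asymmetric J matrix or mismatched dimensions are rejected with the
#' offending field named.
#'
#' @param path JSON file path.
#' @return A [spin_system()].
#' @export
read_spin_system <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("spectrometer_MHz", "spins", "J_Hz")) {
    if (is.null(x[[field]])) stop("spin system JSON: missing '", field, "'")
  }
  spins <- x$spins
  if (is.null(spins$shift_ppm)) {
    stop("spin system JSON: missing 'spins[].shift_ppm'")
  }
  n <- length(spins$shift_ppm)
  T2 <- spins$T2_s
  if (is.null(T2)) {
    warning("spin system JSON: no 'T2_s' given, defaulting to 1.0 s")
    T2 <- rep(1, n)
  } else if (anyNA(T2)) {
    warning("spin system JSON: missing T2_s entries default to 1.0 s")
    T2[is.na(T2)] <- 1
  }
  J <- matrix(unlist(x$J_Hz), n, n, byrow = TRUE)
  if (max(abs(J - t(J))) > 1e-9) {
    bad <- which(abs(J - t(J)) > 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("spin system JSON: J_Hz[%d][%d] != J_Hz[%d][%d]",
                 bad[1], bad[2], bad[2], bad[1]))
  }
  labels <- spins$label
  if (is.null(labels)) labels <- paste0("H", seq_len(n))
  carrier <- if (is.null(x$carrier_ppm)) mean(spins$shift_ppm) else
    x$carrier_ppm
  spin_system(spins$shift_ppm, J, spectrometer_MHz = x$spectrometer_MHz,
              carrier_ppm = carrier, T2_s = T2, labels = labels)
}

#' Write a spin system to JSON
#'
#' @param system a [spin_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(system, path) {
  obj <- list(
    spectrometer_MHz = system$spectrometer_MHz,
    carrier_ppm = system$carrier_ppm,
    spins = data.frame(label = system$labels,
                       shift_ppm = system$shift_ppm,
                       T2_s = system$T2_s),
    J_Hz = system$J_Hz)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read acquisition parameters from JSON
#'
#' The JSON mirrors the fields of [sequence_params()]; `psyche` is a
#' nested object mirroring [psyche_params()]. `selected_band` is either
#' a two-element array `[center_ppm, width_ppm]` or an object
#' `{"spins": [...]}`.
#'
#' @param path JSON file path.
#' @return A [sequence_params()].
#' @export
read_sequence_params <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  psy <- if (is.null(x$psyche)) psyche_params() else
    do.call(psyche_params, x$psyche)
  band <- x$selected_band
  if (is.list(band) && !is.null(band$spins)) {
    band <- list(spins = band$spins)
  }
  args <- x[setdiff(names(x), c("psyche", "selected_band"))]
  do.call(sequence_params,
          c(list(selected_band = band, psyche = psy), args))
}

#' Write acquisition parameters to JSON
#'
#' @param params a [sequence_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequence_params <- function(params, path) {
  obj <- unclass(params)
  obj$psyche <- unclass(obj$psyche)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save or load raw pseudo-3D data
#'
#' The raw dataset (complex array plus metadata) is stored as an RDS
#' container, the package's native raw format.
#'
#' @param raw a `raw_dataset`.
#' @param path file path.
#' @return `path` / the `raw_dataset`.
#' @export
write_raw_dataset <- function(raw, path) {
  saveRDS(raw, path, version = 2)
  invisible(path)
}

#' @rdname write_raw_dataset
#' @export
read_raw_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "raw_dataset")) stop("not a raw_dataset file")
  x
}

#' Export a coupling table
#'
#' @param table a `coupling_table` from [extract_couplings()].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_coupling_table <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}
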