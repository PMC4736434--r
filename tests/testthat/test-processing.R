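test_that("chunk assembly is chunk-major and validates durations", {
  sys <- canned_system("AX")
  par <- sequence_params(selected_band = c(4.2, 0.1), n1 = 2, SW1_Hz = 50,
                         n2 = 4, SW2_Hz = 50, points_per_chunk = 8,
                         SW_acq_Hz = 400, chunk_mode = "aligned")
  raw <- run_psychedelic(sys, par)
  ps <- assemble_chunks(raw)
  expect_equal(dim(ps$data), c(2, 2, 32))
  expect_equal(ps$data[1, 1, 9:16], raw$data[1, 1, 2, ])  # chunk-major
  raw_bad <- raw
  raw_bad$params$SW2_Hz <- 60
  expect_error(assemble_chunks(raw_bad), "1/SW2")
  # half_first convention: first half chunk + full chunks
  par2 <- sequence_params(selected_band = c(4.2, 0.1), n1 = 2, SW1_Hz = 50,
                          n2 = 4, SW2_Hz = 50, points_per_chunk = 8,
                          SW_acq_Hz = 400, chunk_mode = "half_first")
  ps2 <- assemble_chunks(run_psychedelic(sys, par2))
  expect_equal(dim(ps2$data)[3], 4 + 3 * 8)
})

test_that("a single uncoupled spin assembles into a continuous FID", {
  sys <- spin_system(4.3, 0, 500, carrier_ppm = 4.0, T2_s = 1)  # 150 Hz
  par <- sequence_params(selected_band = list(spins = integer(0)), n1 = 1,
                         SW1_Hz = 50, n2 = 6, SW2_Hz = 50,
                         points_per_chunk = 8, SW_acq_Hz = 400)
  raw <- suppressWarnings(run_psychedelic(sys, par))
  ps <- assemble_chunks(raw)
  fid <- ps$data[1, 1, ]
  tt <- (seq_along(fid) - 1) * ps$dwell
  model <- fid[1] * exp((2i * pi * 150 - 1) * tt)
  expect_lt(max(Mod(fid - model)) / Mod(fid[1]), 1e-8)
})

test_that("chunking sidebands of a decoupled doublet stay below 10%", {
  sys <- canned_system("AX")
  # no selection: a pure shift spectrum; J = 7 within chunks only
  par <- sequence_params(selected_band = list(spins = integer(0)), n1 = 1,
                         SW1_Hz = 50, n2 = 24, SW2_Hz = 50,
                         points_per_chunk = 40, SW_acq_Hz = 2000)
  raw <- suppressWarnings(run_psychedelic(sys, par))
  spec <- suppressWarnings(psychedelic_spectrum(raw = raw, tilt = FALSE))
  y <- spec$intensity[1, ]
  main <- which.min(abs(spec$f2_hz - 100))  # A at 100 Hz
  h_main <- max(y[abs(spec$f2_hz - 100) < 5])
  for (sb in c(50, 150)) {  # +/- SW2 sidebands of the A line
    h_sb <- max(abs(y[abs(spec$f2_hz - sb) < 5]))
    expect_lt(h_sb / h_main, 0.10)
  }
})

test_that("echo/antiecho recombination follows the construction", {
  t1 <- (0:7) / 50
  f <- exp(2i * pi * 30 * (0:15) / 400)
  SN <- outer(exp(2i * pi * 5 * t1), f)
  SR <- outer(exp(-2i * pi * 5 * t1), f)
  ps <- structure(list(data = array(c(SN, SR), c(2, 8, 16))[c(1, 2), , ],
                       types = c("N", "R"), t1 = t1, dwell = 1 / 400,
                       SW1_Hz = 50, params = NULL, system = NULL,
                       selected = integer(0)),
                  class = "pure_shift_td")
  # hand-build the array with type as the first index
  arr <- array(0i, c(2, 8, 16)); arr[1, , ] <- SN; arr[2, , ] <- SR
  ps$data <- arr
  pk <- pk_recombine(ps)
  expect_equal(pk$cos, outer(cos(2 * pi * 5 * t1), f))
  expect_equal(pk$sin, outer(sin(2 * pi * 5 * t1), f))
  # omega = 0: sine part identically zero
  arr0 <- array(0i, c(2, 8, 16)); arr0[1, , ] <- outer(rep(1, 8), f)
  arr0[2, , ] <- arr0[1, , ]
  ps$data <- arr0
  expect_equal(max(Mod(pk_recombine(ps)$sin)), 0)
  ps$types <- c("N")
  expect_error(pk_recombine(ps), "both N and R")
})

test_that("ft2d produces calibrated absorption spectra", {
  # delta FID -> flat spectrum
  arr <- array(0i, c(2, 2, 32)); arr[, , 1] <- 1
  ps <- structure(list(data = arr, types = c("N", "R"), t1 = (0:1) / 50,
                       dwell = 1 / 400, SW1_Hz = 50, params = NULL,
                       system = NULL, selected = integer(0)),
                  class = "pure_shift_td")
  spec <- ft2d(pk_recombine(ps), zero_fill = 1, lb2_hz = 0)
  expect_lt(diff(range(spec$intensity[1, ])) /
              max(abs(spec$intensity[1, ])), 1e-9)
  # single exponential: Lorentzian at 100 Hz with FWHM 1/(pi T2) + lb
  T2 <- 1
  tt <- (0:2047) / 400
  arr2 <- array(0i, c(2, 1, 2048))
  arr2[1, 1, ] <- exp((2i * pi * 100 - 1 / T2) * tt)
  arr2[2, 1, ] <- arr2[1, 1, ]
  ps2 <- structure(list(data = arr2, types = c("N", "R"), t1 = 0,
                        dwell = 1 / 400, SW1_Hz = 50, params = NULL,
                        system = NULL, selected = integer(0)),
                   class = "pure_shift_td")
  spec2 <- ft2d(pk_recombine(ps2), zero_fill = 2, lb2_hz = 0)
  pkpos <- spec2$f2_hz[which.max(spec2$intensity[1, ])]
  expect_lt(abs(pkpos - 100), 400 / 4096)
  expect_equal(measure_fwhm(spec2$f2_hz, spec2$intensity[1, ]),
               1 / (pi * T2), tolerance = 0.05)
})

test_that("tilt45 shears intensity to (f1, f2 - f1) with sub-bin accuracy", {
  # synthetic delta peaks on a hand-built spectrum
  f1 <- seq(-25, 24.5, by = 0.5)
  f2 <- seq(0, 399.5, by = 0.5)
  m <- matrix(0, length(f1), length(f2))
  m[which(f1 == 3.5), which(f2 == 203.5)] <- 1
  m[which(f1 == 0), which(f2 == 100)] <- 1
  spec <- structure(list(intensity = m, quadrants = list(RR = m),
                         f1_hz = f1, f2_hz = f2, f2_ppm = f2 / 500,
                         phase0 = 0, tilt = FALSE, mode = "pk",
                         system = NULL, selected = integer(0),
                         log = character(0)),
                    class = "spectrum2d")
  tl <- tilt45(spec)
  i1 <- which(f1 == 3.5)
  expect_equal(f2[which.max(tl$intensity[i1, ])], 200)
  i0 <- which(f1 == 0)
  expect_equal(f2[which.max(tl$intensity[i0, ])], 100)  # f1 = 0 unmoved
  expect_error(tilt45(tl), "already tilted")
  # linearity: shear commutes with scaling and addition
  spec2 <- spec; spec2$intensity <- 2 * spec$intensity + 1
  spec2$quadrants <- list(RR = spec2$intensity)
  tl2 <- tilt45(spec2)
  expect_equal(tl2$intensity, 2 * tl$intensity + 1, tolerance = 1e-9)
})

test_that("AX doublet rows align at the partner shift after tilt", {
  sys <- canned_system("AX")
  par <- sequence_params(selected_band = c(4.2, 0.1), n1 = 64, SW1_Hz = 50,
                         n2 = 16, SW2_Hz = 50, points_per_chunk = 40,
                         SW_acq_Hz = 2000)
  spec <- psychedelic_spectrum(sys, par)
  df2 <- spec$f2_hz[2] - spec$f2_hz[1]
  # refined F2 peak position of each doublet row, searched near the X
  # shift (the selected spin leaves a ghost elsewhere in the row)
  win <- abs(spec$f2_hz - 300) < 15
  pos <- vapply(c(-3.5, 3.5), function(f1) {
    i <- which.min(abs(spec$f1_hz - f1))
    row <- spec$intensity[i, ]
    j <- which(win)[which.max(row[win])]
    a <- row[j - 1]; b <- row[j]; cc <- row[j + 1]
    spec$f2_hz[j] + df2 * 0.5 * (a - cc) / (a - 2 * b + cc)
  }, numeric(1))
  expect_lt(abs(pos[1] - pos[2]), 0.1 * df2)
  expect_lt(abs(mean(pos) - 300), df2)
})

test_that("f1_trace interpolates columns of tilted spectra", {
  sys <- axu_system()
  par <- sequence_params(selected_band = c(4.2, 0.1), n1 = 64, SW1_Hz = 50,
                         n2 = 16, SW2_Hz = 50, points_per_chunk = 40,
                         SW_acq_Hz = 2000)
  spec <- psychedelic_spectrum(sys, par)
  expect_error(f1_trace(ft2d(pk_recombine(assemble_chunks(
    run_psychedelic(sys, par)))), f2_hz = 50), "tilted")
  tr <- f1_trace(spec, f2_hz = 250)  # uncoupled spin U
  expect_equal(tr$f1_hz[which.max(tr$intensity)], 0, tolerance = 0.4)
  trX <- f1_trace(spec, f2_ppm = 4.6)
  pks <- local_max_positions(trX$f1_hz, trX$intensity, 0.4)
  expect_equal(pks, c(-3.5, 3.5), tolerance = 0.12)
  expect_error(f1_trace(spec, f2_hz = 5000), "outside")
  # trace through an empty region stays at the numerical floor
  tr0 <- f1_trace(spec, f2_hz = 170)
  expect_lt(max(abs(tr0$intensity)), 0.02 * max(abs(trX$intensity)))
})

test_that("absorption vs phasetwist lineshape diagnostics", {
  sys <- canned_system("AX")
  par <- sequence_params(selected_band = c(4.2, 0.1), n1 = 64, SW1_Hz = 50,
                         n2 = 16, SW2_Hz = 50, points_per_chunk = 40,
                         SW_acq_Hz = 2000)
  raw <- run_psychedelic(sys, par)
  ps <- assemble_chunks(raw)
  expect_lt(phasetwist_ratio(ft2d(pk_recombine(ps))), 0.02)
  expect_gt(phasetwist_ratio(ft2d(ps)), 0.5)
})
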