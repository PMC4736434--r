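# Shared fixture builders. Everything is generated in code; sizes are kept
# small so individual tests stay fast.

# AX plus an uncoupled bystander spin, selection on A
axu_system <- function() {
  spin_system(c(4.2, 4.6, 5.0), jmat3(c(1, 2, 7)), 500, carrier_ppm = 4.5,
              T2_s = 1.5, labels = c("A", "X", "U"))
}

jmat3 <- function(...) {
  J <- matrix(0, 3, 3)
  for (tr in list(...)) {
    J[tr[1], tr[2]] <- J[tr[2], tr[1]] <- tr[3]
  }
  J
}

# small but fully working acquisition for 2-3 spin systems
quick_params <- function(..., n1 = 8, SW1_Hz = 50, n2 = 4, SW2_Hz = 50,
                         points_per_chunk = 16, SW_acq_Hz = 800) {
  sequence_params(..., n1 = n1, SW1_Hz = SW1_Hz, n2 = n2, SW2_Hz = SW2_Hz,
                  points_per_chunk = points_per_chunk,
                  SW_acq_Hz = SW_acq_Hz)
}

# production-like acquisition used for J recovery on spread-out systems
recovery_params <- function(selected, seed = 1, noise_sigma = 0) {
  sequence_params(selected_band = list(spins = selected), n1 = 128,
                  SW1_Hz = 40, n2 = 12, SW2_Hz = 40, points_per_chunk = 60,
                  SW_acq_Hz = 2400, noise_sigma = noise_sigma, seed = seed)
}

# J errors for all partners of the selected spin + false-doublet count
recover_couplings <- function(sys, sel, params = recovery_params(sel),
                              threshold = 0.1) {
  spec <- suppressWarnings(psychedelic_spectrum(sys, params))
  tab <- extract_couplings(spec, threshold = threshold)
  off <- offsets_hz(sys)
  errs <- c()
  false_d <- 0L
  for (j in setdiff(seq_len(sys$n_spins), sel)) {
    row <- tab[!tab$selected & abs(tab$f2_hz - off[j]) < 5, , drop = FALSE]
    if (nrow(row) > 1) row <- row[which.min(abs(row$f2_hz - off[j])), ]
    Jtrue <- max(sys$J_Hz[sel, j])
    if (Jtrue > 0) {
      errs <- c(errs, if (nrow(row) && row$multiplicity[1] == "d")
        abs(row$J1_hz[1] - Jtrue) else NA_real_)
    } else if (nrow(row) && any(row$multiplicity == "d")) {
      false_d <- false_d + 1L
    }
  }
  list(errors = errs, false_doublets = false_d, table = tab)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(abs(b)), tol)
}

# single-quantum stick spectrum from an eigendecomposed Hamiltonian
sq_lines <- function(H, ops) {
  V <- H$vectors
  B <- Conj(t(V)) %*% ops$Fp %*% V
  lam <- H$values / (2 * pi)
  idx <- which(Mod(B) > 1e-9, arr.ind = TRUE)
  data.frame(freq = lam[idx[, 1]] - lam[idx[, 2]],
             intensity = Mod(B[idx])^2)
}

local_max_positions <- function(f, y, rel) {
  n <- length(y)
  idx <- which(y > rel * max(y) & y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  f[idx]
}

f2_unshifted <- function(M, sw) {
  k <- 0:(M - 1)
  k[k >= ceiling(M / 2)] <- k[k >= ceiling(M / 2)] - M
  k * sw / M
}

shifted_freqs_test <- function(M, sw) sort(f2_unshifted(M, sw))
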