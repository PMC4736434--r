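test_that("spin operators obey angular momentum algebra", {
  for (n in 1:3) {
    ops <- spin_operators(n)
    for (i in seq_len(n)) {
      sp <- ops$spin[[i]]
      expect_lt(max(Mod(sp$Ix %*% sp$Iy - sp$Iy %*% sp$Ix - 1i * sp$Iz)),
                1e-12)
    }
    if (n >= 2) {
      # operators of different spins commute
      comm <- ops$spin[[1]]$Ix %*% ops$spin[[2]]$Iy -
        ops$spin[[2]]$Iy %*% ops$spin[[1]]$Ix
      expect_lt(max(Mod(comm)), 1e-12)
      expect_equal(Re(sum(diag(ops$spin[[1]]$Iz %*% ops$spin[[2]]$Iz))), 0)
      expect_equal(Re(sum(diag(ops$spin[[1]]$Iz %*% ops$spin[[1]]$Iz))),
                   2^n / 4)
    }
  }
  expect_equal(sort(Re(diag(spin_operators(1)$spin[[1]]$Iz))),
               c(-0.5, 0.5))
  expect_error(spin_operators(11), "1 to 10")
})

test_that("weak Hamiltonian reproduces first-order multiplet lines", {
  sys <- spin_system(c(4.0, 4.4), matrix(c(0, 10, 10, 0), 2), 500,
                     carrier_ppm = 4.0)  # offsets 0 and 200 Hz
  H <- free_hamiltonian(sys, "weak")
  lines <- sq_lines(H, spin_operators(2))
  expect_equal(sort(lines$freq), c(-5, 5, 195, 205), tolerance = 1e-9)
})

test_that("single-spin Hamiltonian eigenvalues are +/- half the offset", {
  sys <- spin_system(4.2, 0, 500, carrier_ppm = 4.0)  # 100 Hz
  H <- free_hamiltonian(sys, "strong")
  expect_equal(sort(H$values) / (2 * pi), c(-50, 50), tolerance = 1e-9)
})

test_that("AB quartet matches the closed form including roofing", {
  dnu <- 10; J <- 10
  sys <- canned_system("AB")
  H <- free_hamiltonian(sys, "strong")
  li <- sq_lines(H, spin_operators(2))
  C <- sqrt(dnu^2 + J^2)
  expected <- sort(c(-C / 2 - J / 2, -C / 2 + J / 2,
                     C / 2 - J / 2, C / 2 + J / 2))
  ord <- order(li$freq)
  expect_equal(li$freq[ord], expected, tolerance = 1e-6)
  # intensity roofing: outer/inner = (C - J)/(C + J)
  inten <- li$intensity[ord]
  expect_equal(inten[1] / inten[2], (C - J) / (C + J), tolerance = 1e-6)
  expect_equal(inten[4] / inten[3], (C - J) / (C + J), tolerance = 1e-6)
})

test_that("strong-model spectra converge to weak-model spectra", {
  J <- 10
  pos_for <- function(model, ratio) {
    sys <- spin_system(c(4.0, 4.0 + ratio * J / 500),
                       matrix(c(0, J, J, 0), 2), 500, carrier_ppm = 4.0)
    li <- sq_lines(free_hamiltonian(sys, model), spin_operators(2))
    sort(li$freq[li$intensity > 0.01])
  }
  rms100 <- sqrt(mean((pos_for("strong", 100) - pos_for("weak", 100))^2))
  expect_lt(rms100, 0.01 * J)
  rms5 <- sqrt(mean((pos_for("strong", 5) - pos_for("weak", 5))^2))
  expect_gt(rms5, rms100)  # deviation grows as coupling strengthens
})

test_that("asymmetric J matrices are rejected", {
  expect_error(spin_system(c(1, 2), matrix(c(0, 3, 4, 0), 2)), "symmetric")
  expect_error(spin_system(c(1, 2), matrix(c(1, 3, 3, 0), 2)), "diagonal")
  expect_error(spin_system(c(1, 2), matrix(c(0, 3, 3, 0), 2), T2_s = -1),
               "positive")
})

test_that("thermal state is longitudinal and silent", {
  sys <- canned_system("AX")
  ops <- spin_operators(2)
  rho <- thermal_state(sys, ops)
  for (i in 1:2) {
    expect_gt(Re(sum(diag(rho %*% ops$spin[[i]]$Iz))), 0)
    expect_equal(Re(sum(diag(rho %*% ops$spin[[i]]$Ix))), 0)
  }
  expect_equal(Mod(detect_signal(rho, ops)), 0)
})

test_that("free evolution is unitary and matches product-operator forms", {
  sys <- spin_system(4.2, 0, 500, carrier_ppm = 4.0)  # 100 Hz
  ops <- spin_operators(1)
  H <- free_hamiltonian(sys, "strong", ops)
  rho <- ops$spin[[1]]$Ix + 0i
  expect_equal(evolve_state(rho, H, 0), rho)
  r2 <- evolve_state(rho, H, 0.0025)  # quarter period at 100 Hz
  expect_lt(abs(Re(sum(diag(r2 %*% ops$spin[[1]]$Ix)))), 1e-10)
  expect_equal(abs(Re(sum(diag(r2 %*% ops$spin[[1]]$Iy)))) * 2, 1,
               tolerance = 1e-9)
  # spectrum of rho is preserved (purity conserved)
  expect_equal(sum(Mod(r2)^2), sum(Mod(rho)^2), tolerance = 1e-12)

  # AX antiphase buildup at t = 1/(2J): cos(pi J t) = 0 empties the
  # in-phase terms, the full magnitude sits in antiphase (both
  # quadratures, since the shift also rotates in the transverse plane)
  ax <- canned_system("AX")
  ops2 <- spin_operators(2)
  Hw <- free_hamiltonian(ax, "weak", ops2)
  rho1 <- ops2$spin[[1]]$Ix + 0i
  rt <- evolve_state(rho1, Hw, 1 / (2 * 7))
  coef <- function(op) Re(sum(diag(rt %*% op)))  # ops here have Tr(op^2)=1
  s1 <- ops2$spin[[1]]; z2 <- ops2$spin[[2]]$Iz
  m_in <- sqrt(coef(s1$Ix)^2 + coef(s1$Iy)^2)
  m_anti <- sqrt(coef(2 * s1$Ix %*% z2)^2 + coef(2 * s1$Iy %*% z2)^2)
  expect_lt(m_in, 1e-9)
  expect_equal(m_anti, 1, tolerance = 1e-9)
  expect_error(evolve_state(rho, H, -1), "non-negative")
})

test_that("detection convention and linearity", {
  ops <- spin_operators(2)
  expect_equal(detect_signal(ops$spin[[1]]$Ix + 0i, ops), 1 + 0i)
  expect_equal(detect_signal(ops$spin[[1]]$Iz + 0i, ops), 0 + 0i)
  anti <- 2 * ops$spin[[1]]$Ix %*% ops$spin[[2]]$Iz
  expect_equal(Mod(detect_signal(anti, ops)), 0)
  expect_equal(detect_signal(3 * ops$spin[[1]]$Ix + 0i, ops), 3 + 0i)
})

test_that("coherence filter keeps chosen orders and is idempotent", {
  ops <- spin_operators(2)
  rho <- ops$spin[[1]]$Ix + 0i
  f <- coherence_filter(rho, -1, ops)
  expect_equal(f, ops$spin[[1]]$Im / 2)
  expect_equal(coherence_filter(f, -1, ops), f)
  expect_equal(coherence_filter(rho, c(-2, -1, 0, 1, 2), ops), rho)
  dq <- ops$spin[[1]]$Ip %*% ops$spin[[2]]$Ip
  expect_lt(max(Mod(coherence_filter(dq, c(-1, 0, 1), ops))), 1e-14)
  expect_warning(z <- coherence_filter(rho, integer(0), ops), "empty")
  expect_equal(max(Mod(z)), 0)
})

test_that("T2 envelope gives the expected decay and linewidth", {
  t_ax <- seq(0, 8, by = 1 / 100)
  sig <- rep(1 + 0i, length(t_ax))
  expect_equal(Re(apply_t2_decay(sig, t_ax, 1)[t_ax == 1]), exp(-1))
  expect_equal(apply_t2_decay(sig, t_ax, Inf), sig)
  # FT linewidth of an exponential with T2 = 0.5 s: FWHM = 1/(pi T2)
  s <- apply_t2_decay(exp(2i * pi * 20 * t_ax), t_ax, 0.5)
  S <- Re(stats::fft(c(s * c(0.5, rep(1, length(s) - 1)),
                       complex(4 * length(s)))))
  fr <- seq(0, by = 100 / (5 * length(s)), length.out = 5 * length(s))
  expect_equal(measure_fwhm(fr, S), 1 / (pi * 0.5), tolerance = 0.05)
})
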