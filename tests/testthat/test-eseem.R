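test_that("Larmor frequencies and the proton blind spot match CODATA arithmetic", {
  # 9.5 GHz, g = 2.006: B ~ 0.338 T
  nu_H <- larmor_frequency("1H", 9.5, 2.006)
  nu_D <- larmor_frequency("2H", 9.5, 2.006)
  expect_equal(nu_H, 14.41, tolerance = 2e-3)
  expect_equal(nu_D, 2.21, tolerance = 2e-3)
  # gamma ratio
  expect_equal(nu_D / nu_H, 6.536 / 42.577478518, tolerance = 1e-9)
  # blind spot tau = 2 / nu_H ~ 139 ns, i.e. the customary ~140 ns
  tau <- blind_spot_tau(9.5, 2.006)
  expect_equal(tau, 138.8, tolerance = 1e-3)
  expect_equal(round(tau, -1), 140)
  # frequency -> 0 limit
  expect_equal(larmor_frequency("1H", 0), 0)
  expect_error(larmor_frequency("13C", 9.5), "arg")
})

test_that("stretched-exponential fit recovers known decays", {
  T <- seq(0, 3600, by = 12)
  truth <- list(A = 2.3, tau_d = 2400, beta = 1.3)
  tr <- time_trace(T, truth$A * exp(-(T / truth$tau_d)^truth$beta),
                   unit = "ns")
  fit <- fit_stretched_decay(tr)
  expect_equal(fit$A, truth$A, tolerance = 0.01)
  expect_equal(fit$tau_d, truth$tau_d, tolerance = 0.01 * 2400 / 2400)
  expect_equal(fit$beta, truth$beta, tolerance = 0.01)
  # with a deep modulation riding on it, tau_d still within 10 %
  trm <- simulate_3peseem(eseem_2h(0.4, noise_sd = 0))
  fitm <- fit_stretched_decay(trm)
  expect_equal(fitm$tau_d, 8000, tolerance = 0.1)
})

test_that("flat traces pin the stretch exponent with a warning", {
  T <- seq(0, 1200, by = 12)
  expect_warning(fit <- fit_stretched_decay(time_trace(T, rep(1.5, length(T)),
                                                       unit = "ns")),
                 "flat|lower bound")
  expect_equal(fit$A, 1.5)
})

test_that("modulation normalization identities", {
  T <- seq(0, 2400, by = 12)
  dec <- structure(list(A = 1.7, tau_d = 3000, beta = 1.1),
                   class = "stretched_decay")
  f <- predict(dec, T)
  # V = f -> output identically 0
  out0 <- normalize_modulation(time_trace(T, f, unit = "ns"), dec)
  expect_equal(out0$real, rep(0, length(T)), tolerance = 1e-14)
  # V = f (1 + m) -> output = m exactly
  m <- 0.2 * cos(2 * pi * T / 450)
  outm <- normalize_modulation(time_trace(T, f * (1 + m), unit = "ns"), dec)
  expect_equal(outm$real, m, tolerance = 1e-12)
})

test_that("the full chain is exactly scale-invariant in the echo amplitude", {
  p1 <- eseem_2h(0.25, noise_sd = 0)
  tr1 <- simulate_3peseem(p1)
  tr10 <- time_trace(tr1$t, 10 * tr1$real, imag = tr1$imag, unit = "ns",
                     meta = tr1$meta)
  n1 <- normalize_modulation(tr1, fit_stretched_decay(tr1))
  n10 <- normalize_modulation(tr10, fit_stretched_decay(tr10))
  expect_equal(n1$real, n10$real, tolerance = 1e-6)
})

test_that("spectrum of a pure tone peaks at the tone frequency", {
  T <- seq(0, 12 * 255, by = 12)
  tone <- time_trace(T, cos(2 * pi * 2.2e-3 * T), unit = "ns")
  spec <- eseem_spectrum(tone)
  bin <- spec$freq[2] - spec$freq[1]
  expect_lt(abs(spec$freq[which.max(Mod(spec$spec))] - 2.2), bin)
  # zero input -> zero spectrum
  z <- eseem_spectrum(time_trace(T, rep(0, length(T)), unit = "ns"))
  expect_equal(max(Mod(z$spec)), 0)
  # doubling the zero-fill halves the bin width, peak stays put
  spec4 <- eseem_spectrum(tone, zero_fill_factor = 4)
  expect_equal(spec4$freq[2] - spec4$freq[1], bin / 2, tolerance = 1e-12)
  expect_lt(abs(spec4$freq[which.max(Mod(spec4$spec))] - 2.2), bin)
})

test_that("phase correction undoes a known rotation and never hurts", {
  T <- seq(0, 12 * 255, by = 12)
  tr <- simulate_3peseem(eseem_2h(0.3, noise_sd = 0.005), seed = 8)
  spec <- eseem_spectrum(normalize_modulation(tr, fit_stretched_decay(tr)))
  band <- spec$freq >= 0.5 & spec$freq <= 8
  # rotate an already-corrected spectrum by +30 degrees: the recovered
  # phase must be -30 degrees (mod pi; sign fixed towards absorption)
  base <- phase_correct(spec)
  rotated <- base
  rotated$spec <- base$spec * exp(1i * pi / 6)
  rotated$phase_corrected <- FALSE
  fixed <- phase_correct(rotated)
  wrapped <- (fixed$phase + pi / 6) %% pi
  expect_lt(min(wrapped, pi - wrapped), 0.05)
  # a real, symmetric spectrum needs (to within noise) no rotation
  resym <- base
  resym$phase_corrected <- FALSE
  re_fixed <- phase_correct(resym)
  w0 <- re_fixed$phase %% pi
  expect_lt(min(w0, pi - w0), 0.05)
  # imaginary power never increases
  for (s in 1:3) {
    tr_s <- simulate_3peseem(eseem_2h(0.2, noise_sd = 0.01), seed = s)
    sp <- eseem_spectrum(normalize_modulation(tr_s, fit_stretched_decay(tr_s)))
    before <- sum(Im(sp$spec[band])^2)
    after <- sum(Im(phase_correct(sp)$spec[band])^2)
    expect_lte(after, before + 1e-12)
  }
  expect_error(phase_correct(fixed), "already")
})

test_that("deuterium intensity is monotone in the modulation amplitude", {
  ints <- vapply(seq(0, 0.5, by = 0.1), function(k) {
    p <- eseem_params(couplings = list(list(nucleus = "2H", k = k,
                                            freq = NULL)),
                      noise_sd = 0.01)
    eseem_accessibility(simulate_3peseem(p, seed = 5))$intensity
  }, 1)
  expect_true(all(diff(ints) > 0))
  # small-k regime: doubling k roughly doubles the intensity
  expect_equal(ints[3] / ints[2], 2, tolerance = 0.15)
})

test_that("no deuterium modulation means intensity at the noise floor", {
  p0 <- eseem_2h(0, noise_sd = 0.01)
  acc <- eseem_accessibility(simulate_3peseem(p0, seed = 3))
  expect_lte(acc$intensity, 3 * acc$error)
})

test_that("identical conditions give a null percent change within errors", {
  for (s in 1:3) {
    a <- eseem_accessibility(simulate_3peseem(eseem_2h(0.1), seed = 300 + s))
    b <- eseem_accessibility(simulate_3peseem(eseem_2h(0.1), seed = 400 + s))
    ch <- percent_change(a, b)
    expect_lt(abs(ch$percent), 3 * ch$error)
    # propagated relative error at least each input relative error
    expect_gte(ch$error / 100,
               max(a$error / a$intensity, b$error / b$intensity) * 0.99)
  }
})

test_that("percent change arithmetic", {
  mk <- function(i, e) structure(list(intensity = i, error = e, nu_D = 2.2,
                                      condition = "x"),
                                 class = "accessibility_result")
  expect_equal(percent_change(mk(2, 0.1), mk(2, 0.1))$percent, 0)
  expect_equal(percent_change(mk(1.28, 0.01), mk(1, 0.01))$percent, 28)
  expect_error(percent_change(mk(1, 0.1), mk(0, 0.1)), "positive")
})

test_that("accessibility readout demands phase correction and in-range nu_D", {
  tr <- simulate_3peseem(eseem_2h(0.3, noise_sd = 0))
  spec <- eseem_spectrum(normalize_modulation(tr, fit_stretched_decay(tr)))
  expect_error(deuterium_accessibility(spec), "phase")
  spec_pc <- phase_correct(spec)
  bad <- spec_pc
  bad$meta$freq_GHz <- 500  # nu_D far above the Nyquist range
  expect_error(deuterium_accessibility(bad), "outside")
})
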