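test_that("noiseless zero-depth DEER trace equals the analytic background", {
  r <- seq(2, 5, by = 0.05)
  pr <- distance_distribution(r, dnorm(r, 3, 0.2))
  p <- deer_params(mod_depth = 0, noise_sd = 0,
                   time_axis = seq(0, 2, by = 0.01))
  tr <- simulate_deer(pr, p)
  expect_equal(tr$real, deer_background(tr$t, p$bg_rate, p$bg_dimension),
               tolerance = 1e-14)
})

test_that("simulated DEER starts at V(0) = 1 before noise for any P(r)", {
  r <- seq(1.6, 7, by = 0.05)
  for (mid in c(2.2, 3.7, 5.5)) {
    pr <- distance_distribution(r, dnorm(r, mid, 0.3))
    tr <- simulate_deer(pr, deer_params(mod_depth = 0.42, noise_sd = 0))
    expect_equal(tr$real[1], 1, tolerance = 1e-12)
  }
})

test_that("a delta-like P(r) oscillates at the perpendicular dipolar frequency", {
  # narrow distribution at 2.5 nm: nu_perp = D / 2.5^3 ~ 3.33 MHz
  r <- seq(2.3, 2.7, by = 0.002)
  pr <- distance_distribution(r, dnorm(r, 2.5, 0.004))
  tr <- simulate_deer(pr, deer_params(mod_depth = 0.3, bg_rate = 0,
                                      noise_sd = 0,
                                      time_axis = seq(0, 3, by = 0.004)))
  # oscillating part, dominant frequency via FFT
  s <- tr$real - mean(tr$real)
  n <- length(s)
  spec <- Mod(stats::fft(s))[1:(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) / (n * 0.004)  # MHz
  nu_expected <- dipolar_constant() / 2.5^3
  expect_equal(freq[which.max(spec)], nu_expected, tolerance = 0.05)
})

test_that("DEER simulation is bit-reproducible given a seed", {
  r <- seq(2, 5, by = 0.05)
  pr <- distance_distribution(r, dnorm(r, 3, 0.2))
  a <- simulate_deer(pr, deer_params(noise_sd = 0.02), seed = 9)
  b <- simulate_deer(pr, deer_params(noise_sd = 0.02), seed = 9)
  expect_identical(a$real, b$real)
  # and does not disturb the global RNG stream
  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(simulate_deer(pr, deer_params(), seed = 1))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(deer_params(mod_depth = 1.2), "\\[0, 1\\]")
  expect_error(deer_params(noise_sd = -1), "non-negative")
  expect_error(deer_params(time_axis = c(0.5, 1)), "start at 0")
  expect_error(eseem_params(tau = -5), "positive")
  expect_error(eseem_params(couplings = list(list(nucleus = "2H", k = 2))),
               "\\[0, 1\\]")
  expect_error(eseem_params(decay = list(A = 1, tau_d = 100, beta = 3)),
               "beta")
})

test_that("unmodulated ESEEM trace is a pure stretched-exponential decay", {
  p <- eseem_params(couplings = list(list(nucleus = "2H", k = 0, freq = NULL)),
                    noise_sd = 0)
  tr <- simulate_3peseem(p)
  d <- p$decay
  expect_equal(tr$real, d$A * exp(-(tr$t / d$tau_d)^d$beta),
               tolerance = 1e-14)
})

test_that("a nucleus at its blind spot contributes no modulation", {
  # omega * tau = 2 pi m  <=>  tau = m / nu
  nu <- 2.2  # MHz
  tau_blind <- 2 / nu * 1e3  # ns
  p <- eseem_params(tau = tau_blind,
                    couplings = list(list(nucleus = "2H", k = 0.4,
                                          freq = nu)),
                    noise_sd = 0)
  tr <- simulate_3peseem(p)
  d <- p$decay
  expect_equal(tr$real, d$A * exp(-(tr$t / d$tau_d)^d$beta),
               tolerance = 1e-10)
})

test_that("simulated 2H modulation shows up at its frequency in the spectrum", {
  p <- eseem_params(tau = 140,
                    couplings = list(list(nucleus = "2H", k = 0.4,
                                          freq = 2.2)),
                    noise_sd = 0)
  tr <- simulate_3peseem(p)
  spec <- phase_correct(eseem_spectrum(normalize_modulation(
    tr, fit_stretched_decay(tr))))
  pk_freq <- spec$freq[which.max(Mod(spec$spec) * (spec$freq > 0.5))]
  bin <- spec$freq[2] - spec$freq[1]
  expect_lt(abs(pk_freq - 2.2), 2 * bin)
})

test_that("ESEEM simulation is reproducible given a seed", {
  a <- simulate_3peseem(eseem_params(noise_sd = 0.02), seed = 4)
  b <- simulate_3peseem(eseem_params(noise_sd = 0.02), seed = 4)
  expect_identical(a$real, b$real)
  expect_identical(a$imag, b$imag)
})
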