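test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  wl <- 315:405
  poly <- 3 + 0.5 * wl - 0.002 * wl^2
  sp <- data.frame(wavelength = wl, intensity = poly)
  sm <- smooth_spectrum(sp, window = 5, order = 2)
  expect_equal(sm$intensity, poly, tolerance = 1e-9)
  expect_error(smooth_spectrum(sp, window = 4), "odd")
  expect_error(smooth_spectrum(sp, window = 3, order = 2), "order")
  expect_error(smooth_spectrum(sp[1:3, ], window = 5), "larger")
})

test_that("smoothing preserves a noisy peak position and damps white noise", {
  wl <- 315:405
  shape <- exp(-0.5 * ((wl - 340) / 18)^2)
  set.seed(12)
  noise <- rnorm(91, 0, 0.01)
  sp <- data.frame(wavelength = wl, intensity = shape + noise)
  sm <- smooth_spectrum(sp, window = 5, order = 2)
  expect_lte(abs(lambda_max(sm)$lambda_max - 340), 1)
  # quadratic 5-point SG kernel passes 595/1225 of white-noise variance
  h <- c(-3, 12, 17, 12, -3) / 35
  var_factor <- sum(h^2)
  expect_equal(var_factor, 595 / 1225, tolerance = 1e-12)
  resid_sm <- sm$intensity - shape
  expect_equal(var(resid_sm[5:87]) / var(noise[5:87]), var_factor,
               tolerance = 0.35)
})

test_that("lambda_max ties break blue and edges are flagged", {
  wl <- 315:405
  gauss <- data.frame(wavelength = wl,
                      intensity = exp(-0.5 * ((wl - 340) / 12)^2))
  lm1 <- lambda_max(gauss)
  expect_equal(lm1$lambda_max, 340)
  expect_false(lm1$tie || lm1$at_edge)
  twin <- data.frame(wavelength = wl, intensity = rep(0.1, 91))
  twin$intensity[wl == 338] <- 1
  twin$intensity[wl == 352] <- 1
  lm2 <- lambda_max(twin)
  expect_equal(lm2$lambda_max, 338)
  expect_true(lm2$tie)
  edge <- data.frame(wavelength = wl, intensity = seq(0, 1,
                                                      length.out = 91))
  expect_true(lambda_max(edge)$at_edge)
  expect_error(lambda_max(data.frame(wavelength = wl,
                                     intensity = rep(1, 91))), "flat")
})

test_that("Stern-Volmer ratios: identity, inverse response and ladder checks", {
  sim <- simulate_quench(0.6, noise_cv = 0, seed = 2)
  # KI identical to KCl: all ratios 1
  tit0 <- stern_volmer_ratio(sim$kcl, sim$kcl)
  expect_equal(tit0$f_ratio, rep(1, nrow(tit0)), tolerance = 1e-12)
  # halving one KI well's intensity doubles that ratio
  ki <- sim$kcl
  ki$intensity[ki$conc == 0.25] <- ki$intensity[ki$conc == 0.25] / 2
  tit2 <- stern_volmer_ratio(ki, sim$kcl)
  expect_equal(tit2$f_ratio[tit2$conc == 0.25], 2, tolerance = 1e-9)
  expect_equal(tit2$f_ratio[tit2$conc == 0], 1, tolerance = 1e-9)
  bad <- sim$ki[sim$ki$conc != 0.05, ]
  expect_error(stern_volmer_ratio(bad, sim$kcl), "ladders")
})

test_that("noiseless forward-model titrations land on the exact line", {
  sim <- simulate_quench(0.47, noise_cv = 0, seed = 5)
  tit <- stern_volmer_ratio(sim$ki, sim$kcl)
  expect_equal(tit$f_ratio, 1 + 0.47 * tit$conc, tolerance = 1e-9)
  fit <- fit_ksv(tit)
  expect_equal(fit$ksv, 0.47, tolerance = 1e-9)
  expect_false(fit$shrunk)
  expect_equal(fit$fitted_range, max(tit$conc))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("KSV estimation is invariant under intensity rescaling", {
  sim <- simulate_quench(0.8, noise_cv = 0.02, seed = 6)
  f1 <- fit_ksv(stern_volmer_ratio(sim$ki, sim$kcl))
  ki2 <- sim$ki; ki2$intensity <- ki2$intensity * 37.5
  kcl2 <- sim$kcl; kcl2$intensity <- kcl2$intensity * 37.5
  f2 <- fit_ksv(stern_volmer_ratio(ki2, kcl2))
  expect_equal(f1$ksv, f2$ksv, tolerance = 1e-12)
})

test_that("two-population curvature triggers the initial-window shrink", {
  sim <- simulate_quench(0, populations = list(ksv = c(0.1, 5),
                                               w = c(0.5, 0.5)),
                         noise_cv = 0.005, seed = 7)
  tit <- stern_volmer_ratio(sim$ki, sim$kcl)
  fit <- fit_ksv(tit)
  expect_true(fit$shrunk)
  expect_lt(fit$fitted_range, max(tit$conc))
  expect_gte(fit$n_used, 3)
  # free-intercept diagnostic is reported alongside
  expect_true(is.finite(fit$diagnostic$slope))
})

test_that("the 95% CI covers the truth at its nominal rate", {
  ksv <- 0.5
  x <- seq(0.05, 0.5, by = 0.05)
  cover <- 0
  for (r in 1:400) {
    set.seed(r)
    y <- 1 + ksv * x + rnorm(length(x), 0, 0.01)
    f <- fit_ksv(data.frame(conc = x, f_ratio = y))
    if (f$ci95[1] <= ksv && ksv <= f$ci95[2]) cover <- cover + 1
  }
  expect_gte(cover / 400, 0.92)
  expect_lte(cover / 400, 0.98)
})
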