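make_series <- function(I_list, sigma_list, s = seq(0.01, 0.2,
                                                    length.out = 40)) {
  frames <- mapply(function(I, sg)
    scattering_profile(s, rep_len(I, length(s)), rep_len(sg, length(s))),
    I_list, sigma_list, SIMPLIFY = FALSE)
  frame_series(frames)
}

test_that("averaging identical frames keeps I and shrinks sigma by sqrt(n)", {
  ser <- make_series(rep(list(2), 4), rep(list(0.2), 4))
  avg <- average_frames(ser, 1:4)
  expect_equal(avg$intensity, rep(2, 40))
  expect_equal(avg$sigma, rep(0.2 / 2, 40))
})

test_that("equal-sigma averaging of I = 1 and I = 3 gives 2 everywhere", {
  ser <- make_series(list(1, 3), list(0.1, 0.1))
  expect_equal(average_frames(ser, 1:2)$intensity, rep(2, 40))
})

test_that("heterogeneous-sigma averaging matches the weighted-mean oracle", {
  set.seed(42)
  s <- seq(0.01, 0.2, length.out = 25)
  I <- replicate(5, runif(25, 1, 5), simplify = FALSE)
  sg <- replicate(5, runif(25, 0.05, 0.5), simplify = FALSE)
  ser <- frame_series(mapply(scattering_profile, list(s), I, sg,
                             SIMPLIFY = FALSE))
  avg <- average_frames(ser, 1:5)
  # brute-force oracle, point by point
  for (k in c(1, 7, 25)) {
    w <- vapply(sg, function(x) 1 / x[k]^2, numeric(1))
    Ik <- vapply(I, `[`, numeric(1), k)
    expect_equal(avg$intensity[k], sum(w * Ik) / sum(w), tolerance = 1e-12)
    expect_equal(avg$sigma[k], 1 / sqrt(sum(w)), tolerance = 1e-12)
  }
  expect_error(average_frames(ser, integer(0)), "empty")
  expect_error(average_frames(ser, c(1, 99)), "not in series")
})

test_that("buffer subtraction: identity gives zeros, sigmas add in quadrature", {
  s <- seq(0.01, 0.1, length.out = 20)
  a <- scattering_profile(s, rep(5, 20), rep(3, 20))
  b <- scattering_profile(s, rep(5, 20), rep(4, 20))
  sub <- subtract_buffer(a, b)
  expect_equal(sub$intensity, rep(0, 20))
  expect_equal(sub$sigma, rep(5, 20))   # 3-4-5
  self_sub <- subtract_buffer(a, a)
  expect_equal(self_sub$sigma, rep(3 * sqrt(2), 20))
  b2 <- scattering_profile(s + 1e-3, rep(5, 20), rep(4, 20))
  expect_error(subtract_buffer(a, b2), "different s-grids")
})

test_that("averaging and subtraction commute (linear operations)", {
  set.seed(7)
  s <- seq(0.01, 0.15, length.out = 30)
  mk <- function() scattering_profile(s, runif(30, 1, 3), runif(30, 0.1, 0.2))
  samp <- frame_series(replicate(3, mk(), simplify = FALSE))
  buf <- average_frames(frame_series(replicate(3, mk(), simplify = FALSE)),
                        1:3)
  path1 <- subtract_buffer(average_frames(samp, 1:3), buf)
  per_frame <- lapply(samp$frames, subtract_buffer, buffer = buf)
  # direct weighted mean of the per-frame differences with the same weights
  w <- vapply(samp$frames, function(f) 1 / f$sigma^2, numeric(30))
  I2 <- rowSums(vapply(seq_len(3), function(i)
    per_frame[[i]]$intensity * w[, i], numeric(30))) / rowSums(w)
  expect_equal(path1$intensity, I2, tolerance = 1e-12)
})

test_that("error rescaling divides sigma only and scales chi2 by divisor^2", {
  s <- seq(0.01, 0.1, length.out = 20)
  expt <- scattering_profile(s, exp(-100 * s^2), rep(0.4, 20))
  model <- scattering_profile(s, exp(-110 * s^2), rep(1, 20))
  expect_equal(rescale_errors(expt, 1)$sigma, expt$sigma)
  resc <- rescale_errors(expt, 2)
  expect_equal(resc$sigma, rep(0.2, 20))
  expect_equal(resc$intensity, expt$intensity)
  chi_before <- chi2_fit(model, expt)$chi2
  chi_after <- chi2_fit(model, resc)$chi2
  expect_equal(chi_after / chi_before, 4, tolerance = 1e-9)
  expect_equal(chi2_fit(model, resc)$chi2_raw, chi_before,
               tolerance = 1e-9)
  expect_error(rescale_errors(expt, 0), "positive")
})

test_that("rg_trace is constant on identical frames and flags failures", {
  s <- seq(0.004, 0.06, length.out = 60)
  sphere <- scattering_profile(s, sphere_form_factor(s, 50), rep(1e-4, 60))
  flat <- scattering_profile(s, rep(1, 60), rep(1e-4, 60))
  ser <- frame_series(list(sphere, sphere, flat, sphere))
  tr <- rg_trace(ser)
  expect_equal(tr$ok, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tr$Rg[1], tr$Rg[2], tolerance = 1e-12)
  expect_equal(tr$Rg[1], tr$Rg[4], tolerance = 1e-12)
  # rising/flat frame fails the Guinier fit but does not abort the trace
  expect_true(is.na(tr$Rg[3]) && nzchar(tr$note[3]))
  expect_equal(tr$Rg[1], sqrt(3 / 5) * 50, tolerance = 0.02)
})

test_that("rg_trace variation on a noisy single-species series stays small", {
  s <- seq(0.004, 0.06, length.out = 80)
  I0 <- 100
  I_true <- I0 * sphere_form_factor(s, 50)
  set.seed(13)
  frames <- replicate(12, {
    sig <- 0.005 * I_true
    scattering_profile(s, I_true + rnorm(80, 0, sig), sig)
  }, simplify = FALSE)
  tr <- rg_trace(frame_series(frames))
  expect_true(all(tr$ok))
  expect_lt(sd(tr$Rg) / mean(tr$Rg), 0.01)
})
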