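test_that("Debye closed forms: single scatterer and two-point interference", {
  s <- seq(0.01, 0.3, length.out = 50)
  one <- debye_intensity(hybrid_model(matrix(c(1, 2, 3), 1), 2.5), s)
  expect_equal(one$intensity, rep(2.5^2, 50))
  d <- 25
  two <- debye_intensity(hybrid_model(rbind(c(0, 0, 0), c(0, 0, d)),
                                      c(1.5, 1.5)), s)
  expect_equal(two$intensity, 2 * 1.5^2 * (1 + sin(s * d) / (s * d)),
               tolerance = 1e-12)
})

test_that("I(0) equals the squared total contrast", {
  set.seed(5)
  xyz <- matrix(rnorm(90, sd = 15), ncol = 3)
  f <- runif(30, -2, 3)
  m <- hybrid_model(xyz, f)
  I <- debye_intensity(m, c(0, 0.05))
  expect_equal(I$intensity[1], sum(f)^2, tolerance = 1e-9)
})

test_that("Debye intensity is invariant under rigid motion", {
  set.seed(6)
  xyz <- matrix(rnorm(150, sd = 20), ncol = 3)
  f <- runif(50, 0.5, 2)
  s <- seq(0.01, 0.2, length.out = 30)
  I1 <- debye_intensity(hybrid_model(xyz, f), s)$intensity
  R <- pdcflex:::rotation_matrix(c(1, 2, -1), 1.1)
  xyz2 <- sweep(xyz %*% t(R), 2, c(10, -40, 7), "+")
  I2 <- debye_intensity(hybrid_model(xyz2, f), s)$intensity
  expect_equal(I1, I2, tolerance = 1e-10)
})

test_that("histogram acceleration matches the exact loop on 3000 scatterers", {
  set.seed(3)
  xyz <- matrix(rnorm(9000, sd = 20), ncol = 3)
  f <- rep(1, 3000)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  s <- seq(0.002, 3 / rg, length.out = 60)
  e <- debye_intensity(hybrid_model(xyz, f), s, method = "exact")
  h <- debye_intensity(hybrid_model(xyz, f), s, method = "histogram")
  expect_lt(max(abs(h$intensity / e$intensity - 1)), 0.005)
})

test_that("contrast assignment follows the matched-solvent and sign rules", {
  atoms <- data.frame(element = c("C", "N", "O"), x = c(0, 3, 6),
                      y = 0, z = 0)
  corona <- build_corona(NULL, corona_geometry(a = 12, b = 15, t = 4),
                         spacing = 4)
  # region density equal to solvent: exactly zero corona contrast
  m0 <- assign_contrast(NULL, corona, rho_tail = rho_water,
                        rho_head = rho_water)
  expect_equal(m0$f, rep(0, nrow(corona$positions)))
  # DDM densities vs water: negative tail, positive head contrast
  m <- assign_contrast(atoms, corona, rho_tail = 0.277, rho_head = 0.520)
  expect_true(all(m$f[m$label == "corona-tail"] < 0))
  expect_true(all(m$f[m$label == "corona-head"] > 0))
  # linearity: total contrast equals the hand-summed parts
  f_protein <- c(6, 7, 8) - rho_water * c(16.44, 2.49, 9.13)
  f_corona <- ifelse(corona$region == "tail",
                     (0.277 - rho_water), (0.520 - rho_water)) * 4^3
  expect_equal(sum(m$f), sum(f_protein) + sum(f_corona), tolerance = 1e-12)
  expect_error(assign_contrast(data.frame(element = "Xx", x = 0, y = 0,
                                          z = 0)), "unknown element")
})

test_that("chi2 fitting solves scale and offset and normalizes by N - p", {
  s <- seq(0.01, 0.2, length.out = 40)
  I <- exp(-300 * s^2)
  model <- scattering_profile(s, I, rep(1, 40))
  expt1 <- scattering_profile(s, I, rep(0.01, 40))
  f1 <- chi2_fit(model, expt1)
  expect_equal(f1$chi2, 0, tolerance = 1e-20)
  expect_equal(f1$scale, 1)
  expt2 <- scattering_profile(s, 2 * I, rep(0.01, 40))
  f2 <- chi2_fit(model, expt2)
  expect_equal(f2$chi2, 0, tolerance = 1e-20)
  expect_equal(f2$scale, 2)
  # offset fitting
  expt3 <- scattering_profile(s, 3 * I + 0.25, rep(0.01, 40))
  f3 <- chi2_fit(model, expt3, fit_offset = TRUE)
  expect_equal(f3$scale, 3, tolerance = 1e-9)
  expect_equal(f3$offset, 0.25, tolerance = 1e-9)
  expect_equal(f3$p, 2)
  # invariance under common rescaling of model, data and sigma
  lam <- 7.3
  f4 <- chi2_fit(scattering_profile(s, lam * I, rep(1, 40)),
                 scattering_profile(s, lam * (I + 0.005), lam * 0.01 +
                                      numeric(40)))
  f5 <- chi2_fit(scattering_profile(s, I, rep(1, 40)),
                 scattering_profile(s, I + 0.005, rep(0.01, 40)))
  expect_equal(f4$chi2, f5$chi2, tolerance = 1e-9)
})

test_that("chi2 of a true model under its own noise is calibrated near 1", {
  s <- seq(0.01, 0.2, length.out = 60)
  I <- 10 * exp(-400 * s^2)
  sig <- 0.02 * I + 1e-4
  model <- scattering_profile(s, I, rep(1, 60))
  set.seed(31)
  chis <- replicate(100, {
    expt <- scattering_profile(s, I + rnorm(60, 0, sig), sig)
    chi2_fit(model, expt)$chi2
  })
  expect_gt(mean(chis), 0.9)
  expect_lt(mean(chis), 1.1)
})
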