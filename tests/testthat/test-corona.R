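test_that("corona geometry validates its five parameters", {
  g <- corona_geometry(a = 31, b = 23, e = 1.5, t = 4.8, omega = 110)
  expect_equal(g$b * g$e, 34.5)
  expect_equal(g$b / g$e, 23 / 1.5)
  expect_error(corona_geometry(a = -1, b = 20, t = 4), "positive")
  expect_error(corona_geometry(a = 30, b = 20, e = 0.8, t = 4), "e must")
  expect_error(corona_geometry(a = 30, b = 20, t = 4, omega = 400),
               "omega")
  # omega is meaningless (stored as 0) for circular cross sections
  expect_equal(corona_geometry(a = 30, b = 20, e = 1, t = 4,
                               omega = 45)$omega, 0)
})

test_that("shell thickness >= half-extent labels every point head", {
  g <- corona_geometry(a = 20, b = 18, t = 25)
  cor <- build_corona(NULL, g, spacing = 3)
  expect_equal(cor$n_tail, 0L)
  expect_equal(unique(cor$region), "head")
})

test_that("protein-free circular corona volume matches the Monte-Carlo oracle", {
  g <- corona_geometry(a = 30, b = 24, e = 1, t = 5)
  cor <- build_corona(NULL, g, spacing = 3)
  lattice_vol <- nrow(cor$positions) * cor$per_point_volume
  # MC oracle over the bounding box
  set.seed(77)
  n_mc <- 2e5
  pts <- cbind(runif(n_mc, -24, 24), runif(n_mc, -24, 24),
               runif(n_mc, -15, 15))
  inside <- (pts[, 1] / 24)^2 + (pts[, 2] / 24)^2 <= 1
  mc_vol <- mean(inside) * 48 * 48 * 30
  expect_equal(lattice_vol, mc_vol, tolerance = 0.05)
  # analytic elliptic cylinder as a second check
  expect_equal(lattice_vol, pi * 24 * 24 * 30, tolerance = 0.05)
})

test_that("head and tail volumes partition the corona; tail shrinks with t", {
  g1 <- corona_geometry(a = 30, b = 24, e = 1.3, t = 4)
  c1 <- build_corona(NULL, g1, spacing = 3)
  expect_equal(c1$n_tail + c1$n_head, nrow(c1$positions))
  g2 <- corona_geometry(a = 30, b = 24, e = 1.3, t = 7)
  c2 <- build_corona(NULL, g2, spacing = 3)
  expect_lt(c2$n_tail, c1$n_tail)
  expect_equal(nrow(c1$positions), nrow(c2$positions))  # same envelope
})

test_that("point count is invariant under omega for circular cross sections", {
  counts <- vapply(c(0, 30, 77, 145), function(w) {
    g <- corona_geometry(a = 24, b = 20, e = 1, t = 4, omega = 0)
    g$omega <- w   # bypass the e == 1 normalization to probe symmetry
    nrow(build_corona(NULL, g, spacing = 3)$positions)
  }, numeric(1))
  expect_equal(length(unique(counts)), 1L)
})

test_that("detergent count estimates follow the volume arithmetic", {
  g <- corona_geometry(a = 30, b = 24, e = 1, t = 5)
  cor <- build_corona(NULL, g, spacing = 1.5)
  est <- estimate_detergent_count(cor, v_tail = 350, v_head = 505)
  expect_equal(est$from_tail, cor$n_tail * 1.5^3 / 350)
  expect_equal(est$from_head, cor$n_head * 1.5^3 / 505)
  expect_equal(est$count, min(est$from_tail, est$from_head))
  expect_equal(est$interval, sort(c(est$from_tail, est$from_head)))
  # doubling all linear dimensions gives ~8x the count
  g8 <- corona_geometry(a = 60, b = 48, e = 1, t = 10)
  est8 <- estimate_detergent_count(build_corona(NULL, g8, spacing = 1.5),
                                   v_tail = 350, v_head = 505)
  expect_equal(est8$from_tail / est$from_tail, 8, tolerance = 0.10)
})

test_that("a truth geometry scores chi2 ~ 0 on its own noiseless curve", {
  fx <- toy_fixture()
  model <- assign_contrast(fx$ori$atoms, fx$corona,
                           rho_tail = fx$dd$rho_tail,
                           rho_head = fx$dd$rho_head)
  s <- seq(0.01, 0.2, length.out = 50)
  curve <- debye_intensity(model, s)
  expt <- scattering_profile(s, curve$intensity,
                             pmax(0.01 * curve$intensity, 1e-9))
  grid <- list(a = fx$geom$a, b = fx$geom$b, e = fx$geom$e, t = fx$geom$t,
               omega = fx$geom$omega)
  fit <- fit_corona(fx$ori, expt, grid, rho_tail = fx$dd$rho_tail,
                    rho_head = fx$dd$rho_head, spacing = 4)
  expect_lt(fit$table$chi2[1], 0.01)
  expect_equal(fit$best$a, fx$geom$a)
})

test_that("corona building excludes protein-occupied space", {
  fx <- toy_fixture()
  prot <- as.matrix(fx$ori$atoms[, c("x", "y", "z")])
  pos <- fx$corona$positions
  dmin <- apply(pos, 1, function(p) sqrt(min(colSums((t(prot) - p)^2))))
  expect_gt(min(dmin), 1.8)
})
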