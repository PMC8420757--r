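test_that("Rflex is 0 for a delta and exactly 100 for a uniform histogram", {
  expect_equal(rflex(rep(25, 40), support = c(20, 30)), 0)
  # one sample per bin: perfectly uniform histogram
  mids <- seq(20.1, 29.9, length.out = 50)
  expect_equal(rflex(mids, bins = 50, support = c(20, 30)), 100)
  expect_error(rflex(numeric(0)), "empty")
})

test_that("Rflex is invariant under affine rescaling and permutation", {
  set.seed(8)
  rg <- runif(200, 20, 45)
  r0 <- rflex(rg)
  expect_equal(rflex(3 * rg + 7, support = 3 * range(rg) + 7), r0)
  expect_equal(rflex(sample(rg)), r0)
  # weighted version: duplicating a sample equals doubling its weight
  w <- rep(1, 200); w[5] <- 2
  expect_equal(rflex(c(rg, rg[5]), support = range(rg)),
               rflex(rg, weights = w, support = range(rg)))
})

test_that("pool retention reflects how crowded the geometry is", {
  # spacious geometry (long linker, small domains, no corona): almost all
  # drawn conformers are admissible -- only the rare draw that lands one
  # body on the other is discarded
  spec <- toy_protein_spec(n_tm_helices = 2, tm_length = 12,
                           soluble_radius = 8, linker_length = 24,
                           open_distance = 40, seed = 3)
  tp <- make_toy_protein(spec)
  dec <- decompose(tp$atoms, list(tp$domains$linker))
  pool <- generate_pool(dec, 100, rng_seed = 4)
  expect_gte(pool$retained, 90L)
  # crowded geometry (detergent shell around the TM body): markedly lower
  fx <- toy_fixture()
  pool2 <- generate_pool(fx$dec, 100, rng_seed = 4)
  expect_lt(pool2$retained, pool$retained)
})

test_that("retained pool conformers pass the brute-force clash oracle", {
  fx <- toy_fixture()
  pool <- generate_pool(fx$dec, 60, rng_seed = 9)
  expect_gt(pool$retained, 10)
  for (i in seq_len(min(5, pool$retained))) {
    cf <- pool$conformers[[i]]
    cc <- conformer_coords(cf)
    xyz <- rbind(cc$xyz, cc$corona_xyz)
    radii <- c(rep(1.7, nrow(cc$xyz)), rep(1.5, nrow(cc$corona_xyz)))
    group <- c(cc$group, rep(fx$dec$tm_body, nrow(cc$corona_xyz)))
    expect_equal(brute_clashes(xyz, radii, group, 0.4), 0L)
  }
  expect_true(all(is.finite(pool$rg)) && all(pool$rg > 0))
})

test_that("pool generation and selection are bit-reproducible under seeds", {
  fx <- toy_fixture()
  p1 <- generate_pool(fx$dec, 40, rng_seed = 12)
  p2 <- generate_pool(fx$dec, 40, rng_seed = 12)
  expect_identical(p1$rg, p2$rg)
  expect_identical(p1$curves, p2$curves)
  expt <- scattering_profile(pmax(p1$s, 1e-12), p1$curves[, 1],
                             pmax(0.01 * p1$curves[, 1], 1e-9))
  cfg <- list(pop = 20, gens = 10)
  s1 <- select_ensemble(p1, expt, ga_cfg = cfg, rng_seed = 3)
  s2 <- select_ensemble(p1, expt, ga_cfg = cfg, rng_seed = 3)
  expect_identical(s1$chi2, s2$chi2)
  expect_identical(s1$indices, s2$indices)
})

test_that("selection beats or matches the best single pool conformer", {
  fx <- toy_fixture()
  pool <- generate_pool(fx$dec, 80, rng_seed = 15)
  # data from a half-and-half mixture of two pool members
  I_mix <- 0.5 * pool$curves[, 3] + 0.5 * pool$curves[, 17]
  expt <- scattering_profile(pmax(pool$s, 1e-12), I_mix,
                             pmax(0.01 * I_mix, 1e-9))
  sel <- select_ensemble(pool, expt, ga_cfg = list(pop = 60, gens = 60),
                         rng_seed = 2)
  # chi2 of each singleton ensemble
  keep <- expt$s <= 0.1
  single_best <- min(apply(pool$curves[keep, ], 2, function(M) {
    E <- expt$intensity[keep]; sig <- expt$sigma[keep]
    w <- 1 / sig^2
    sc <- sum(w * M * E) / sum(w * M^2)
    sum(((sc * M - E) / sig)^2) / (sum(keep) - 1)
  }))
  expect_lte(sel$chi2, single_best + 1e-9)
  expect_equal(sum(sel$weights), 1, tolerance = 1e-12)
  expect_true(all(sel$weights >= 0))
  expect_true(sel$rflex_selected >= 0 && sel$rflex_selected <= 100)
})

test_that("a planted-truth pool selects a near-delta at the true Rg", {
  fx <- toy_fixture()
  pool <- generate_pool(fx$dec, 150, rng_seed = 21)
  truth <- 42
  I_true <- pool$curves[, truth]
  expt <- scattering_profile(pmax(pool$s, 1e-12), I_true,
                             pmax(0.01 * I_true, 1e-9))
  sel <- select_ensemble(pool, expt, ga_cfg = list(pop = 80, gens = 80),
                         rng_seed = 7)
  expect_lt(sel$chi2, 0.5)
  expect_lt(abs(weighted.mean(pool$rg[sel$indices], sel$weights) -
                  pool$rg[truth]), 2)
  expect_lt(sel$rflex_selected, sel$rflex_pool)
})
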