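test_that("decomposition partitions residues into bodies and segments", {
  fx <- toy_fixture()
  dec <- fx$dec
  expect_length(dec$bodies, 2)
  expect_length(dec$segments, 1)
  all_res <- sort(c(unlist(lapply(dec$bodies, `[[`, "resids")),
                    unlist(lapply(dec$segments, `[[`, "resids"))))
  expect_equal(all_res, sort(unique(dec$atoms$resid)))
  seg <- dec$segments[[1]]
  expect_false(is.na(seg$anchor_before))
  expect_false(is.na(seg$anchor_after))
  # TM body is the low-z body; corona attached there
  expect_lt(mean(dec$atoms$z[dec$bodies[[dec$tm_body]]$idx]),
            mean(dec$atoms$z[dec$bodies[[dec$mobile_body]]$idx]))
  expect_length(dec$corona_f, nrow(dec$corona$positions))
})

test_that("an empty flexible set yields a single rigid body (no-op case)", {
  fx <- toy_fixture()
  dec <- decompose(fx$ori$atoms, list())
  expect_length(dec$bodies, 1)
  expect_length(dec$segments, 0)
  start <- new_conformer(dec)
  expect_error(genetic_refine(start, scattering_profile(
    seq(0.01, 0.1, length.out = 20), rep(1, 20), rep(0.1, 20))),
    "no flexible segment")
})

test_that("terminal flexible ranges get one anchor and are rebuilt as tails", {
  fx <- toy_fixture()
  n <- nrow(fx$ori$atoms)
  dec <- decompose(fx$ori$atoms,
                   list(c(1, 4), fx$closed$domains$linker))
  seg1 <- dec$segments[[1]]
  expect_true(is.na(seg1$anchor_before))
  expect_false(is.na(seg1$anchor_after))
  cf <- pdcflex:::rebuild_linkers(new_conformer(dec))
  expect_false(is.null(cf))
  tail_xyz <- cf$linkers[[1]]
  expect_equal(nrow(tail_xyz), 4)
  # chain continuity into the anchor
  gap <- sqrt(sum((tail_xyz[4, ] -
                     unlist(dec$atoms[seg1$anchor_after,
                                      c("x", "y", "z")]))^2))
  expect_equal(gap, 3.8, tolerance = 1e-6)
})

test_that("zero-magnitude perturbation is the identity", {
  fx <- toy_fixture()
  start <- new_conformer(fx$dec)
  expect_identical(perturb(start, 0), start)
})

test_that("perturbed conformers always satisfy the chain and clash invariants", {
  fx <- toy_fixture()
  start <- pdcflex:::rebuild_linkers(new_conformer(fx$dec))
  set.seed(19)
  n_moved <- 0
  for (i in 1:40) {
    cf <- perturb(start, magnitude = 30)
    if (isTRUE(attr(cf, "rejected"))) next
    n_moved <- n_moved + 1
    link <- cf$linkers[[1]]
    seg <- fx$dec$segments[[1]]
    cc <- conformer_coords(cf)
    chain <- rbind(cc$xyz[seg$anchor_before, ], link,
                   cc$xyz[seg$anchor_after, ])
    bonds <- sqrt(rowSums(diff(chain)^2))
    expect_true(all(abs(bonds - 3.8) < 0.4))
    expect_equal(pdcflex:::conformer_clashes(cf), 0)
  }
  expect_gt(n_moved, 20)   # moves are mostly accepted at this magnitude
})

test_that("a bridge beyond the linker reach is rejected, not silently built", {
  p0 <- c(0, 0, 0); p1 <- c(0, 0, 100)
  expect_null(pdcflex:::grow_bridge(p0, p1, n = 5))   # 6 bonds x 3.8 < 100
  ok <- pdcflex:::grow_bridge(p0, c(0, 0, 20), n = 5)
  expect_false(is.null(ok))
})

test_that("clash counting matches a brute-force oracle on random clouds", {
  set.seed(23)
  for (rep in 1:3) {
    xyz <- matrix(runif(1500, 0, 40), ncol = 3)   # 500 atoms, crowded
    group <- sample(c(0L, 1L, 2L), 500, replace = TRUE)
    radii <- rep(1.7, 500)
    expect_equal(check_clashes(xyz, cutoff = 0.4, group = group),
                 brute_clashes(xyz, radii, group, 0.4))
  }
  # trivial pairs
  expect_equal(check_clashes(rbind(c(0, 0, 0), c(10, 0, 0))), 0)
  expect_equal(check_clashes(rbind(c(0, 0, 0), c(1, 0, 0)),
                             cutoff = 0.4, elements = c("C", "C")), 1)
  expect_error(check_clashes(matrix(0, 1, 3), cutoff = 0), "positive")
})

test_that("refinement is deterministic under a fixed seed and improves monotonically", {
  fx <- toy_fixture()
  start <- new_conformer(fx$dec)
  cf_o <- new_conformer(fx$dec_open)
  s <- seq(0.008, 0.12, length.out = 30)
  tru <- debye_intensity(pdcflex:::conformer_model(cf_o), s)
  expt <- scattering_profile(s, tru$intensity,
                             pmax(0.02 * tru$intensity, 1e-9))
  cfg <- list(pop = 10, gens = 6, top_k = 2)
  r1 <- genetic_refine(start, expt, ga_cfg = cfg, seed = 5)
  r2 <- genetic_refine(start, expt, ga_cfg = cfg, seed = 5)
  expect_identical(r1$chi2, r2$chi2)
  expect_identical(conformer_coords(r1$conformers[[1]])$xyz,
                   conformer_coords(r2$conformers[[1]])$xyz)
  expect_true(all(diff(r1$best_history) <= 1e-12))
})

test_that("a start conformer that generates the data scores chi2 ~ 0 at once", {
  fx <- toy_fixture()
  start <- new_conformer(fx$dec)
  s <- seq(0.008, 0.12, length.out = 30)
  tru <- debye_intensity(pdcflex:::conformer_model(start), s)
  expt <- scattering_profile(s, tru$intensity,
                             pmax(0.02 * tru$intensity, 1e-9))
  res <- genetic_refine(start, expt, ga_cfg = list(pop = 6, gens = 1),
                        seed = 2)
  expect_lt(res$chi2[1], 1e-6)
})

test_that("ranked conformers export as a readable multi-model PDB", {
  fx <- toy_fixture()
  start <- new_conformer(fx$dec)
  s <- seq(0.008, 0.12, length.out = 20)
  tru <- debye_intensity(pdcflex:::conformer_model(start), s)
  expt <- scattering_profile(s, tru$intensity,
                             pmax(0.02 * tru$intensity, 1e-9))
  res <- genetic_refine(start, expt, ga_cfg = list(pop = 6, gens = 1,
                                                   top_k = 3), seed = 2)
  f <- tempfile(fileext = ".pdb"); tf <- tempfile(fileext = ".tsv")
  write_conformers(res, f, tf)
  pdb <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(dim(pdb$xyz)[1], 3)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), 3)
})
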