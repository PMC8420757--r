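# shared fixtures: analytic oracles and cached synthetic models

# uniform random points in a ball of radius R (rejection sampling)
sphere_points <- function(n, R, seed = 1) {
  set.seed(seed)
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    cand <- matrix(stats::runif(3 * n * 2, -R, R), ncol = 3)
    out <- rbind(out, cand[rowSums(cand^2) <= R^2, , drop = FALSE])
  }
  out[seq_len(n), ]
}

# analytic solid-sphere form factor, normalized to I(0) = 1
sphere_form_factor <- function(s, R) {
  u <- s * R
  (3 * (sin(u) - u * cos(u)) / u^3)^2
}

# oracle: dimensionless Kratky peak of the analytic sphere, located by a
# fine scan of x^2 * F(x / sqrt(3/5)) -- independent of the package code
sphere_kratky_peak <- local({
  x <- seq(1, 2.5, by = 1e-4)
  y <- x^2 * sphere_form_factor(x / sqrt(3 / 5), 1)
  i <- which.max(y)
  c(x = x[i], y = y[i])
})

# cached 1e4-point sphere Debye curve (R = 50 A) used by several files
sphere_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      xyz <- sphere_points(10000, 50, seed = 11)
      model <- hybrid_model(xyz, rep(1, nrow(xyz)))
      s <- seq(0.0015, 0.16, length.out = 160)
      curve <- debye_intensity(model, s)
      cache <<- list(xyz = xyz, model = model, curve = curve, R = 50,
                     rg_ref = sqrt(3 / 5) * 50)
    }
    cache
  }
})

# cached toy two-domain protein with corona and decomposition
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dd <- detergent_defaults$DDM
      spec <- toy_protein_spec(seed = 7)
      closed <- make_toy_protein(spec)
      open <- make_toy_protein(spec, state = "open")
      ori <- orient_structure(closed$atoms, list(closed$domains$tm))
      geom <- corona_geometry(a = 33, b = 20, e = 1.2, t = 5, omega = 0,
                              dd$rho_tail, dd$rho_head)
      cor <- build_corona(ori, geom, spacing = 4)
      dec <- decompose(ori$atoms, list(closed$domains$linker), cor,
                       rho_tail = dd$rho_tail, rho_head = dd$rho_head)
      dec_open <- decompose(open$atoms, list(open$domains$linker), cor,
                            rho_tail = dd$rho_tail, rho_head = dd$rho_head)
      cache <<- list(spec = spec, closed = closed, open = open, ori = ori,
                     geom = geom, corona = cor, dec = dec,
                     dec_open = dec_open, dd = dd)
    }
    cache
  }
})

# inter-domain centroid distance of an assembled conformer coordinate set
centroid_distance <- function(dec, xyz) {
  a <- dec$bodies[[dec$tm_body]]$idx
  b <- dec$bodies[[dec$mobile_body]]$idx
  sqrt(sum((colMeans(xyz[a, , drop = FALSE]) -
              colMeans(xyz[b, , drop = FALSE]))^2))
}

# brute-force clash oracle mirroring the documented counting rules
brute_clashes <- function(xyz, radii, group, cutoff) {
  n <- nrow(xyz)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (group[i] == group[j]) {
        if (group[i] > 0) next
        if (abs(i - j) <= 2) next
      }
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (radii[i] + radii[j] - d > cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}
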