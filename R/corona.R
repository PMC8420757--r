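#' Detergent corona torus geometry
#'
#' The five-parameter description of the dummy-atom detergent belt around
#' an oriented membrane protein: an elliptic slab of height `a` centred on
#' the transmembrane region, lateral cross section with major axis `b * e`
#' and minor axis `b / e`, rotated by `omega` about z, with an outer
#' hydrophilic shell of thickness `t` wrapped around the hydrophobic
#' interior.
#'
#' @param a torus height, Angstrom.
#' @param b ellipse scale, Angstrom (major axis `b * e`, minor `b / e`).
#' @param e ellipticity, >= 1. `omega` has no geometric effect for a
#'   circular cross section and is stored as 0 when `e == 1`.
#' @param t hydrophilic shell thickness, Angstrom.
#' @param omega rotation of the ellipse about z, degrees in `[0, 360)`.
#' @param rho_tail,rho_head tail/head electron densities, e per cubic
#'   Angstrom.
#' @export
corona_geometry <- function(a, b, e = 1, t, omega = 0,
                            rho_tail = detergent_defaults$DDM$rho_tail,
                            rho_head = detergent_defaults$DDM$rho_head) {
  if (a <= 0 || b <= 0 || t <= 0) stop("a, b and t must be positive")
  if (e < 1) stop("ellipticity e must be >= 1")
  if (omega < 0 || omega >= 360) stop("omega must lie in [0, 360)")
  if (e == 1) omega <- 0
  structure(list(a = a, b = b, e = e, t = t, omega = omega,
                 rho_tail = rho_tail, rho_head = rho_head),
            class = "corona_geometry")
}

#' @export
print.corona_geometry <- function(x, ...) {
  cat(sprintf(
    "<corona_geometry> a = %g, b.e = %g, b/e = %g, t = %g A, omega = %g deg\n",
    x$a, x$b * x$e, x$b / x$e, x$t, x$omega))
  invisible(x)
}

#' Build the dummy-atom detergent corona
#'
#' Fills the torus defined by a [corona_geometry()] with points of a simple
#' cubic lattice: points with `|z - tm_z_center| <= a/2` lying inside the
#' rotated ellipse and outside the protein exclusion zone. The outermost
#' shell of thickness `t` is labelled `head` (hydrophilic), the interior
#' `tail` (hydrophobic). By default the head shell covers both the lateral
#' rim and the top/bottom annular faces (`axial_head = FALSE` restricts it
#' to the lateral rim; the choice is not derivable from the modelled
#' physics alone and both topologies are supported).
#'
#' @param oriented an [orient_structure()] result (or `NULL` for a
#'   protein-free corona).
#' @param geom a [corona_geometry()].
#' @param spacing lattice constant, Angstrom (default 3.0, coarser than
#'   atomic detail but fine against the 15-35 Angstrom feature sizes).
#' @param axial_head also label the top/bottom faces as head.
#' @param exclusion protein exclusion radius, Angstrom; default 1.8 plus
#'   the lattice half-diagonal.
#' @return An object of class `corona_dummy_atoms`: `positions` (n x 3),
#'   `region` (tail/head), `per_point_volume` (= spacing^3), the geometry
#'   and tail/head point counts.
#' @export
build_corona <- function(oriented, geom, spacing = 3, axial_head = TRUE,
                         exclusion = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(exclusion)) exclusion <- 1.8 + spacing * sqrt(3) / 2
  z0 <- if (is.null(oriented)) 0 else oriented$tm_z_center
  major <- geom$b * geom$e; minor <- geom$b / geom$e
  # cell-centred lattice: each point represents a full spacing^3 voxel, so
  # point count x spacing^3 estimates the torus volume without slab bias
  centred <- function(lo, hi) {
    n <- max(1L, floor((hi - lo) / spacing))
    mid <- (lo + hi) / 2
    mid + spacing * (seq_len(n) - (n + 1) / 2)
  }
  gx <- centred(-major, major)
  gy <- centred(-major, major)
  gz <- centred(z0 - geom$a / 2, z0 + geom$a / 2)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  w <- geom$omega * pi / 180
  u <- pts[, 1] * cos(w) + pts[, 2] * sin(w)
  v <- -pts[, 1] * sin(w) + pts[, 2] * cos(w)
  inside <- (u / major)^2 + (v / minor)^2 <= 1
  pts <- pts[inside, , drop = FALSE]
  u <- u[inside]; v <- v[inside]
  if (!is.null(oriented)) {
    prot <- as.matrix(oriented$atoms[, c("x", "y", "z")])
    keep <- min_dist_at_least(pts, prot, exclusion)
    if (!any(keep)) stop("corona entirely occupied by protein")
    pts <- pts[keep, , drop = FALSE]
    u <- u[keep]; v <- v[keep]
  }
  if (!nrow(pts)) stop("empty corona: geometry too small for the lattice")
  mi <- major - geom$t; ni <- minor - geom$t
  lateral_head <- if (mi <= 0 || ni <= 0) rep(TRUE, nrow(pts))
                  else (u / mi)^2 + (v / ni)^2 > 1
  axial <- abs(pts[, 3] - z0) > geom$a / 2 - geom$t
  head <- if (axial_head) lateral_head | axial else lateral_head
  structure(list(positions = unname(pts),
                 region = ifelse(head, "head", "tail"),
                 per_point_volume = spacing^3,
                 geometry = geom, spacing = spacing,
                 n_tail = sum(!head), n_head = sum(head)),
            class = "corona_dummy_atoms")
}

# TRUE for rows of `pts` at distance >= `cut` from every row of `ref`
min_dist_at_least <- function(pts, ref, cut) {
  keep <- rep(TRUE, nrow(pts))
  cut2 <- cut^2
  # chunked to bound memory on large lattices
  step <- max(1L, floor(2e6 / max(nrow(ref), 1)))
  i <- 1L
  while (i <= nrow(pts)) {
    j <- min(i + step - 1L, nrow(pts))
    block <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(ref^2), "+") -
      2 * block %*% t(ref)
    keep[i:j] <- apply(d2, 1, min) >= cut2
    i <- j + 1L
  }
  keep
}

#' @export
print.corona_dummy_atoms <- function(x, ...) {
  cat(sprintf("<corona_dummy_atoms> %d points (%d tail, %d head), %.1f A lattice\n",
              nrow(x$positions), x$n_tail, x$n_head, x$spacing))
  invisible(x)
}

#' Detergent monomers accommodated by a corona
#'
#' Two independent estimates -- hydrophobic volume over the monomer tail
#' volume, and hydrophilic volume over the head volume -- reported as an
#' interval, with the count taken as their minimum (the limiting region).
#'
#' @param corona a [build_corona()] result.
#' @param v_tail,v_head monomer tail/head volumes, cubic Angstrom (see
#'   [detergent_defaults]).
#' @return list with `count`, `from_tail`, `from_head`, `interval`.
#' @export
estimate_detergent_count <- function(corona, v_tail, v_head) {
  if (v_tail <= 0 || v_head <= 0) stop("monomer volumes must be positive")
  tail_vol <- corona$n_tail * corona$per_point_volume
  head_vol <- corona$n_head * corona$per_point_volume
  if (tail_vol + head_vol <= 0) stop("zero corona volume")
  ft <- tail_vol / v_tail; fh <- head_vol / v_head
  list(count = min(ft, fh), from_tail = ft, from_head = fh,
       interval = sort(c(ft, fh)))
}

#' Fit the five corona parameters against a scattering curve
#'
#' Grid search over (a, b, e, t, omega): each candidate geometry is built
#' on the lattice, contrasts assigned, the Debye curve computed on the
#' experimental grid and scored by [chi2_fit()] with a fitted scale.
#' Candidates with `e == 1` are evaluated at `omega = 0` only (the
#' rotation is meaningless for a circular cross section). Results are
#' returned ranked by chi-squared.
#'
#' @param oriented an [orient_structure()] result.
#' @param profile experimental [scattering_profile()].
#' @param grid named list of candidate values for `a`, `b`, `e`, `t`,
#'   `omega`.
#' @param rho_solvent,rho_tail,rho_head electron densities, e per cubic
#'   Angstrom.
#' @param spacing lattice constant passed to [build_corona()].
#' @param axial_head passed to [build_corona()].
#' @param fit_offset passed to [chi2_fit()].
#' @return An object of class `corona_fit`: `table` (one row per feasible
#'   geometry, ranked by `chi2`), `best` geometry and `best_corona`.
#' @export
fit_corona <- function(oriented, profile, grid,
                       rho_solvent = rho_water,
                       rho_tail = detergent_defaults$DDM$rho_tail,
                       rho_head = detergent_defaults$DDM$rho_head,
                       spacing = 3, axial_head = TRUE, fit_offset = FALSE) {
  need <- c("a", "b", "e", "t", "omega")
  if (!all(need %in% names(grid)))
    stop("grid must name a, b, e, t, omega")
  cand <- expand.grid(a = grid$a, b = grid$b, e = grid$e, t = grid$t,
                      omega = grid$omega)
  cand$omega[cand$e == 1] <- 0
  cand <- unique(cand)
  if (!nrow(cand)) stop("empty parameter grid")
  res <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    geom <- try(corona_geometry(cand$a[k], cand$b[k], cand$e[k], cand$t[k],
                                cand$omega[k], rho_tail, rho_head),
                silent = TRUE)
    if (inherits(geom, "try-error")) next
    cor <- try(build_corona(oriented, geom, spacing = spacing,
                            axial_head = axial_head), silent = TRUE)
    if (inherits(cor, "try-error")) next
    model <- assign_contrast(oriented$atoms, cor, rho_solvent,
                             rho_tail, rho_head)
    curve <- debye_intensity(model, profile$s)
    fit <- chi2_fit(curve, profile, fit_offset = fit_offset)
    res[[k]] <- data.frame(a = cand$a[k], b = cand$b[k], e = cand$e[k],
                           t = cand$t[k], omega = cand$omega[k],
                           chi2 = fit$chi2, scale = fit$scale,
                           n_points = nrow(cor$positions))
  }
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) stop("no feasible corona geometry in grid")
  res <- res[order(res$chi2), ]
  rownames(res) <- NULL
  best <- corona_geometry(res$a[1], res$b[1], res$e[1], res$t[1],
                          res$omega[1], rho_tail, rho_head)
  structure(list(table = res, best = best,
                 best_corona = build_corona(oriented, best,
                                            spacing = spacing,
                                            axial_head = axial_head)),
            class = "corona_fit")
}

#' @export
print.corona_fit <- function(x, ...) {
  cat(sprintf("<corona_fit> %d geometries; best chi2 = %.4g\n",
              nrow(x$table), x$table$chi2[1]))
  print(utils::head(x$table, 5))
  invisible(x)
}
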