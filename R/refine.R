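#' Decompose a structure into rigid bodies and flexible segments
#'
#' Splits the modelled residues into rigid bodies (the contiguous runs of
#' residues outside the flexible ranges) joined by flexible segments that
#' are rebuilt as dummy-residue chains during refinement. A detergent
#' corona, when given, is rigidly attached to the transmembrane body (the
#' body with the lowest mean z in the oriented frame). Per-atom scattering
#' contrasts are computed once here so conformers can be scored without
#' re-deriving them.
#'
#' @param atoms atom data.frame with `element`, `x`, `y`, `z`, `resid`
#'   columns (an [orient_structure()] result's `$atoms`, or a
#'   [make_toy_protein()] result's `$atoms`).
#' @param flexible_ranges list of `c(first, last)` residue ranges treated
#'   as flexible (e.g. `list(c(1, 7), c(211, 230), c(544, 550))`).
#' @param corona optional [build_corona()] result, attached to the TM body.
#' @param rho_solvent,rho_tail,rho_head electron densities for contrast
#'   assignment, e per cubic Angstrom.
#' @return An object of class `rigid_body_decomposition`: `atoms`, `f`
#'   (per-atom contrasts), `bodies` (list of atom index sets with residue
#'   ranges), `segments` (flexible segments with their body-side anchor
#'   atom indices), `tm_body`, `mobile_body`, `corona`, `corona_f`.
#' @export
decompose <- function(atoms, flexible_ranges, corona = NULL,
                      rho_solvent = rho_water,
                      rho_tail = detergent_defaults$DDM$rho_tail,
                      rho_head = detergent_defaults$DDM$rho_head) {
  if (!length(flexible_ranges)) flexible_ranges <- list()
  if (!is.list(flexible_ranges) && length(flexible_ranges) == 2)
    flexible_ranges <- list(flexible_ranges)
  res <- sort(unique(atoms$resid))
  flex <- rep(FALSE, length(res))
  for (rng in flexible_ranges) {
    if (rng[1] > rng[2]) stop("invalid flexible range")
    flex <- flex | (res >= rng[1] & res <= rng[2])
  }
  rigid_res <- res[!flex]
  if (!length(rigid_res)) stop("no rigid residues left")
  # contiguous runs of rigid residues (in residue-id space) become bodies
  breaks <- which(diff(rigid_res) > 1)
  run_id <- cumsum(c(1, seq_along(rigid_res)[-1] %in% (breaks + 1)))
  bodies <- lapply(split(rigid_res, run_id), function(rr) {
    idx <- which(atoms$resid %in% rr)
    list(resids = rr, idx = idx)
  })
  names(bodies) <- NULL
  # flexible segments with their body-side anchors
  segments <- lapply(flexible_ranges, function(rng) {
    seg_res <- res[res >= rng[1] & res <= rng[2]]
    if (!length(seg_res)) return(NULL)
    idx <- which(atoms$resid %in% seg_res)
    before <- if ((rng[1] - 1) %in% rigid_res)
      which(atoms$resid == rng[1] - 1)[1] else NA_integer_
    after <- if ((rng[2] + 1) %in% rigid_res)
      which(atoms$resid == rng[2] + 1)[1] else NA_integer_
    if (is.na(before) && is.na(after))
      stop("flexible range ", rng[1], "-", rng[2], " has no anchor")
    list(resids = seg_res, idx = idx, anchor_before = before,
         anchor_after = after)
  })
  segments <- Filter(Negate(is.null), segments)
  for (seg in segments) {
    body_of <- function(i) which(vapply(bodies, function(b) i %in% b$idx,
                                        logical(1)))
    ab <- if (!is.na(seg$anchor_before)) body_of(seg$anchor_before) else NULL
    aa <- if (!is.na(seg$anchor_after)) body_of(seg$anchor_after) else NULL
    if (!is.null(ab) && !is.null(aa) && length(ab) != 1 && length(aa) != 1)
      stop("flexible range splits a body into disconnected fragments")
  }
  f <- element_property(atoms$element, "electrons") -
    rho_solvent * element_property(atoms$element, "volume")
  corona_f <- NULL
  tm_body <- 1L
  if (length(bodies) > 1) {
    meanz <- vapply(bodies, function(b) mean(atoms$z[b$idx]), numeric(1))
    tm_body <- which.min(meanz)
  }
  if (!is.null(corona)) {
    corona_f <- ifelse(corona$region == "tail",
                       (rho_tail - rho_solvent) * corona$per_point_volume,
                       (rho_head - rho_solvent) * corona$per_point_volume)
  }
  mobile <- if (length(bodies) > 1) setdiff(seq_along(bodies), tm_body)[1]
            else NA_integer_
  structure(list(atoms = atoms, f = f, bodies = bodies,
                 segments = segments, tm_body = tm_body,
                 mobile_body = mobile, corona = corona,
                 corona_f = corona_f,
                 xyz = as.matrix(atoms[, c("x", "y", "z")]),
                 vdw = element_property(atoms$element, "vdw")),
            class = "rigid_body_decomposition")
}

#' @export
print.rigid_body_decomposition <- function(x, ...) {
  cat(sprintf("<rigid_body_decomposition> %d bodies, %d flexible segments%s\n",
              length(x$bodies), length(x$segments),
              if (!is.null(x$corona)) ", corona attached" else ""))
  invisible(x)
}

# -- linker chain growth ----------------------------------------------------

# Self-avoiding dummy-residue bridge of n beads between anchors p0 and p1
# with every bond exactly `step` long. The last bead is placed analytically
# on the intersection circle of the two final bonds; earlier beads grow with
# a bias toward the target that tightens as slack runs out. `obstacles` is a
# matrix of coordinates the chain must stay `avoid` away from. Returns NULL
# if the bridge cannot be built.
grow_bridge <- function(p0, p1, n, step = 3.8, obstacles = NULL,
                        avoid = 3.0, max_try = 60) {
  D <- sqrt(sum((p1 - p0)^2))
  if (D > step * (n + 1)) return(NULL)
  obs_t <- prefilter_obstacles(obstacles, (p0 + p1) / 2,
                               D / 2 + step * (n + 1) / 2 + avoid)
  clear <- function(pt, placed) {
    if (!is.null(obs_t) &&
        min((obs_t[1, ] - pt[1])^2 + (obs_t[2, ] - pt[2])^2 +
              (obs_t[3, ] - pt[3])^2) < avoid^2) return(FALSE)
    if (length(placed) > 2) {
      prev <- do.call(rbind, placed[seq_len(length(placed) - 2)])
      if (min(colSums((t(prev) - pt)^2)) < avoid^2) return(FALSE)
    }
    TRUE
  }
  for (attempt in seq_len(max_try)) {
    placed <- list()
    cur <- p0
    ok <- TRUE
    if (n >= 2) {
      for (k in seq_len(n - 1)) {
        m_after <- n + 1 - k        # bonds remaining after bead k
        done <- FALSE
        for (try_k in 1:40) {
          to_t <- p1 - cur
          dt <- sqrt(sum(to_t^2))
          slack <- step * m_after - dt
          wbias <- min(1, max(0.05, 1 - slack / (step * m_after)))
          d <- wbias * (if (dt > 0) to_t / dt else random_unit_vector()) +
            (1 - wbias) * random_unit_vector()
          d <- d / sqrt(sum(d^2))
          cand <- cur + step * d
          dc <- sqrt(sum((p1 - cand)^2))
          # m_after bonds remain after bead k, so p1 must stay reachable;
          # the second-to-last bead must also leave the final two-bond
          # closure window attainable
          lim <- if (k == n - 1) c(0.5, 2 * step - 0.2)
                 else if (k == n - 2) c(0, 3 * step - 0.4)
                 else c(0, step * m_after - 0.05)
          if (dc >= lim[1] && dc <= lim[2] && clear(cand, placed)) {
            placed[[k]] <- cand; cur <- cand; done <- TRUE; break
          }
        }
        if (!done) { ok <- FALSE; break }
      }
      if (!ok) next
      # final bead: random point on the circle at `step` from both cur and p1
      d01 <- p1 - cur
      L <- sqrt(sum(d01^2))
      if (L > 2 * step - 1e-9 || L < 1e-6) next
      mid <- (cur + p1) / 2
      rad <- sqrt(step^2 - (L / 2)^2)
      u <- d01 / L
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v1 <- ref - sum(ref * u) * u; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
      done <- FALSE
      for (try_k in 1:40) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- mid + rad * (cos(th) * v1 + sin(th) * v2)
        if (clear(cand, placed)) { placed[[n]] <- cand; done <- TRUE; break }
      }
      if (!done) next
    } else if (n == 1) {
      if (D > 2 * step - 1e-9) return(NULL)
      mid <- (p0 + p1) / 2
      rad2 <- step^2 - (D / 2)^2
      if (rad2 < 0) return(NULL)
      rad <- sqrt(rad2)
      u <- (p1 - p0) / max(D, 1e-9)
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v1 <- ref - sum(ref * u) * u; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
      done <- FALSE
      for (try_k in 1:40) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- p0 + (p1 - p0) / 2 + rad * (cos(th) * v1 + sin(th) * v2)
        if (clear(cand, list())) { placed[[1]] <- cand; done <- TRUE; break }
      }
      if (!done) next
    }
    if (ok && length(placed) == n)
      return(do.call(rbind, placed))
  }
  NULL
}

# restrict an obstacle matrix to a sphere and pre-transpose it (3 x m)
prefilter_obstacles <- function(obstacles, centre, radius) {
  if (is.null(obstacles) || !nrow(obstacles)) return(NULL)
  d2 <- (obstacles[, 1] - centre[1])^2 + (obstacles[, 2] - centre[2])^2 +
    (obstacles[, 3] - centre[3])^2
  keep <- d2 <= radius^2
  if (!any(keep)) return(NULL)
  t(obstacles[keep, , drop = FALSE])
}

# one-anchored terminal tail of n beads grown away from the body
grow_tail <- function(p0, n, step = 3.8, obstacles = NULL, avoid = 3.0,
                      max_try = 60) {
  obs_t <- prefilter_obstacles(obstacles, p0, step * (n + 1) + avoid)
  for (attempt in seq_len(max_try)) {
    placed <- list()
    cur <- p0
    ok <- TRUE
    for (k in seq_len(n)) {
      done <- FALSE
      for (try_k in 1:40) {
        cand <- cur + step * random_unit_vector()
        near_obs <- !is.null(obs_t) &&
          min((obs_t[1, ] - cand[1])^2 + (obs_t[2, ] - cand[2])^2 +
                (obs_t[3, ] - cand[3])^2) < avoid^2
        near_self <- FALSE
        if (length(placed) > 2) {
          prev <- do.call(rbind, placed[seq_len(length(placed) - 2)])
          near_self <- min(colSums((t(prev) - cand)^2)) < avoid^2
        }
        if (!near_obs && !near_self) {
          placed[[k]] <- cand; cur <- cand; done <- TRUE; break
        }
      }
      if (!done) { ok <- FALSE; break }
    }
    if (ok) return(if (n) do.call(rbind, placed) else
                     matrix(numeric(0), 0, 3))
  }
  NULL
}

# -- conformers -------------------------------------------------------------

#' Assemble the full coordinate set of a conformer
#'
#' Applies the conformer's rigid transform to the mobile body (rotation
#' about the bridging anchor, then translation), keeps the TM body and its
#' corona fixed, and splices in the rebuilt flexible segments.
#'
#' @param conformer a conformer as produced by [new_conformer()],
#'   [perturb()] or [generate_pool()].
#' @return list with `xyz` (atoms, transformed), `corona_xyz` (or `NULL`),
#'   `group` (rigid-body id per atom row; 0 for flexible atoms).
#' @export
conformer_coords <- function(conformer) {
  d <- conformer$decomp
  xyz <- d$xyz
  group <- integer(nrow(xyz))
  for (bi in seq_along(d$bodies)) group[d$bodies[[bi]]$idx] <- bi
  if (!is.na(d$mobile_body) && !is.null(conformer$rotation)) {
    idx <- d$bodies[[d$mobile_body]]$idx
    pv <- conformer$pivot
    xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pv) %*%
                          t(conformer$rotation), 2,
                        pv + conformer$translation, "+")
  }
  for (si in seq_along(d$segments)) {
    li <- conformer$linkers[[si]]
    if (!is.null(li)) xyz[d$segments[[si]]$idx, ] <- li
  }
  cx <- if (!is.null(d$corona)) d$corona$positions else NULL
  list(xyz = xyz, corona_xyz = cx, group = group)
}

#' Create the identity conformer of a decomposition
#'
#' The starting conformer: no body transform, flexible segments at their
#' input coordinates. `pivot` is the TM-side anchor of the first segment
#' bridging the two bodies (rotations are taken about it).
#'
#' @param decomp a [decompose()] result.
#' @export
new_conformer <- function(decomp) {
  pivot <- c(0, 0, 0)
  for (seg in decomp$segments) {
    if (!is.na(seg$anchor_before) && !is.na(seg$anchor_after)) {
      a <- seg$anchor_before
      tm_idx <- decomp$bodies[[decomp$tm_body]]$idx
      anchor <- if (a %in% tm_idx) a else seg$anchor_after
      pivot <- as.numeric(decomp$atoms[anchor, c("x", "y", "z")])
      break
    }
  }
  structure(list(decomp = decomp, rotation = diag(3),
                 translation = c(0, 0, 0), pivot = pivot,
                 linkers = vector("list", length(decomp$segments))),
            class = "conformer_model")
}

#' @export
print.conformer_model <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<conformer_model> body rotation %.1f deg, translation %.2f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

# rebuild all flexible segments of a conformer against its current bodies;
# returns the conformer with new linkers, or NULL if a bridge fails
rebuild_linkers <- function(conformer, step = 3.8, avoid = 3.0) {
  d <- conformer$decomp
  cc <- conformer_coords(conformer)
  body_xyz <- cc$xyz[cc$group > 0, , drop = FALSE]
  obstacles <- rbind(body_xyz, cc$corona_xyz)
  for (si in seq_along(d$segments)) {
    seg <- d$segments[[si]]
    n <- length(seg$idx)
    if (!is.na(seg$anchor_before) && !is.na(seg$anchor_after)) {
      p0 <- cc$xyz[seg$anchor_before, ]
      p1 <- cc$xyz[seg$anchor_after, ]
      li <- grow_bridge(p0, p1, n, step = step, obstacles = obstacles,
                        avoid = avoid)
      if (is.null(li)) return(NULL)
      conformer$linkers[[si]] <- li
    } else {
      anchor <- if (!is.na(seg$anchor_before)) seg$anchor_before
                else seg$anchor_after
      li <- grow_tail(cc$xyz[anchor, ], n, step = step,
                      obstacles = obstacles, avoid = avoid)
      if (is.null(li)) return(NULL)
      if (is.na(seg$anchor_before)) li <- li[rev(seq_len(n)), , drop = FALSE]
      conformer$linkers[[si]] <- li
    }
  }
  conformer
}

#' Randomly perturb a conformer
#'
#' Applies a random rigid-body move to the mobile body -- rotation of at
#' most `magnitude` degrees about a random axis through the bridging
#' anchor, plus a translation of at most `magnitude / 10` Angstrom -- then
#' rebuilds the flexible segments by self-avoiding chain growth and
#' rejects moves that cannot bridge the anchors or that clash. With
#' `magnitude = 0` the conformer is returned unchanged.
#'
#' @param conformer a conformer.
#' @param magnitude maximum rotation, degrees.
#' @param rng_seed optional seed for a deterministic move.
#' @param clash_cutoff van der Waals overlap cutoff, Angstrom.
#' @param max_try resampling attempts before giving up.
#' @return The perturbed conformer; on failure the input conformer with
#'   attribute `rejected = TRUE`.
#' @export
perturb <- function(conformer, magnitude, rng_seed = NULL,
                    clash_cutoff = 0.4, max_try = 25) {
  if (magnitude == 0) return(conformer)
  with_seed(rng_seed, {
    for (a in seq_len(max_try)) {
      cand <- conformer
      ang <- stats::runif(1, 0, magnitude) * pi / 180
      cand$rotation <- rotation_matrix(random_unit_vector(), ang) %*%
        conformer$rotation
      cand$translation <- conformer$translation +
        stats::runif(1, 0, magnitude / 10) * random_unit_vector()
      cand <- rebuild_linkers(cand)
      if (is.null(cand)) next
      if (conformer_clashes(cand, clash_cutoff) == 0) return(cand)
    }
    structure(conformer, rejected = TRUE)
  })
}

# clash count of an assembled conformer (corona has the TM body's group)
conformer_clashes <- function(conformer, cutoff = 0.4) {
  cc <- conformer_coords(conformer)
  d <- conformer$decomp
  radii <- d$vdw
  xyz <- cc$xyz; group <- cc$group
  if (!is.null(cc$corona_xyz)) {
    xyz <- rbind(xyz, cc$corona_xyz)
    radii <- c(radii, rep(1.5, nrow(cc$corona_xyz)))
    group <- c(group, rep(d$tm_body, nrow(cc$corona_xyz)))
  }
  cpp_clash_count(xyz, radii, as.integer(group), cutoff)
}

# Incremental Debye evaluator for one decomposition on a fixed s-grid.
# The TM body and its corona never move, so their pairwise term is computed
# once; per conformer only the mobile-part self term and the mobile-vs-fixed
# cross term are summed. Returns function(conformer) -> intensity vector.
conformer_intensity_fun <- function(decomp, s) {
  fixed_idx <- decomp$bodies[[decomp$tm_body]]$idx
  atoms_xyz <- decomp$xyz
  fixed_xyz <- atoms_xyz[fixed_idx, , drop = FALSE]
  fixed_f <- decomp$f[fixed_idx]
  if (!is.null(decomp$corona)) {
    fixed_xyz <- rbind(fixed_xyz, decomp$corona$positions)
    fixed_f <- c(fixed_f, decomp$corona_f)
  }
  mobile_idx <- setdiff(seq_len(nrow(atoms_xyz)), fixed_idx)
  mobile_f <- decomp$f[mobile_idx]
  s <- pmax(as.numeric(s), 1e-12)
  I_fixed <- cpp_debye_exact(fixed_xyz, fixed_f, s)
  function(conformer) {
    cc <- conformer_coords(conformer)
    mx <- cc$xyz[mobile_idx, , drop = FALSE]
    I_fixed + cpp_debye_exact(mx, mobile_f, s) +
      cpp_debye_cross(mx, mobile_f, fixed_xyz, fixed_f, s)
  }
}

# hybrid model of a conformer, using the decomposition's stored contrasts
conformer_model <- function(conformer) {
  cc <- conformer_coords(conformer)
  d <- conformer$decomp
  xyz <- cc$xyz; f <- d$f
  label <- rep("protein-atom", nrow(xyz))
  if (!is.null(cc$corona_xyz)) {
    xyz <- rbind(xyz, cc$corona_xyz)
    f <- c(f, d$corona_f)
    label <- c(label, paste0("corona-", d$corona$region))
  }
  hybrid_model(xyz, f, label)
}

#' Count van der Waals clashes
#'
#' Number of non-bonded atom pairs whose van der Waals overlap
#' `r_i + r_j - d_ij` exceeds `cutoff`, counted with a cell-list spatial
#' grid. Pairs within the same rigid body (same positive `group` id) are
#' exempt, as are sequence-adjacent atoms of the same flexible chain
#' (same `group <= 0`, index difference <= 2). With no `group` every pair
#' is eligible.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param cutoff overlap threshold, Angstrom (> 0).
#' @param elements element symbols for van der Waals radii (default all
#'   carbon).
#' @param group integer rigid-body ids (non-positive for flexible atoms).
#' @export
check_clashes <- function(xyz, cutoff = 0.4, elements = NULL,
                          group = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- as.matrix(xyz)
  radii <- if (is.null(elements)) rep(1.7, nrow(xyz))
           else element_property(elements, "vdw")
  if (is.null(group)) group <- -seq_len(nrow(xyz))
  cpp_clash_count(xyz, radii, as.integer(group), cutoff)
}

#' Rigid-body refinement by a genetic algorithm
#'
#' Evolves a population of conformers -- rigid-body transforms of the
#' mobile domain with rebuilt flexible linkers -- against an experimental
#' curve. Fitness is the reduced chi-squared of the conformer's Debye
#' curve (scale fitted) plus a clash penalty; selection is by tournament,
#' crossover recombines the parents' body transforms, mutation applies
#' [perturb()], and elitism keeps the best conformers unchanged, so the
#' best fitness is non-increasing across generations. Fully deterministic
#' under a fixed seed.
#'
#' @param start starting conformer ([new_conformer()] of a two-body
#'   decomposition).
#' @param experiment experimental [scattering_profile()].
#' @param ga_cfg list overriding any of: `pop` (60), `gens` (120),
#'   `tournament` (3), `elitism` (2), `p_mut` (0.3), `magnitude` (40,
#'   degrees), `top_k` (5).
#' @param seed RNG seed.
#' @return An object of class `refine_result`: `conformers` (top-k, best
#'   first), `chi2` per returned conformer, `best_history` (best fitness
#'   per generation), and the `provenance` (seed, config, generations).
#' @export
genetic_refine <- function(start, experiment, ga_cfg = list(), seed = 1) {
  if (!length(start$decomp$segments))
    stop("decomposition has no flexible segment: nothing to refine")
  cfg <- utils::modifyList(list(pop = 60, gens = 120, tournament = 3,
                                elitism = 2, p_mut = 0.3, magnitude = 40,
                                top_k = 5), ga_cfg)
  ifun <- conformer_intensity_fun(start$decomp, experiment$s)
  E <- experiment$intensity; sig <- experiment$sigma
  w <- 1 / sig^2
  fitness <- function(cf) {
    M <- ifun(cf)
    sc <- sum(w * M * E) / sum(w * M^2)
    chi2 <- sum(((sc * M - E) / sig)^2) / max(length(M) - 1, 1)
    chi2 + 10 * conformer_clashes(cf)
  }
  with_seed(seed, {
    # keep the start's own linker when it is already valid (a start that
    # generates the data must score chi2 = 0 at generation zero)
    start_ok <- if (conformer_clashes(start) == 0) start
                else rebuild_linkers(start)
    if (is.null(start_ok)) start_ok <- start
    pop <- vector("list", cfg$pop)
    pop[[1]] <- start_ok
    for (i in 2:cfg$pop)
      pop[[i]] <- perturb(start_ok, magnitude = cfg$magnitude)
    fit <- vapply(pop, fitness, numeric(1))
    history <- numeric(cfg$gens)
    for (g in seq_len(cfg$gens)) {
      ord <- order(fit)
      newpop <- pop[ord[seq_len(cfg$elitism)]]
      newfit <- fit[ord[seq_len(cfg$elitism)]]
      while (length(newpop) < cfg$pop) {
        pick <- function() {
          cand <- sample.int(cfg$pop, cfg$tournament)
          cand[which.min(fit[cand])]
        }
        pa <- pop[[pick()]]; pb <- pop[[pick()]]
        child <- pa
        if (stats::runif(1) < 0.5) child$rotation <- pb$rotation
        if (stats::runif(1) < 0.5) child$translation <- pb$translation
        rebuilt <- rebuild_linkers(child)
        child <- if (is.null(rebuilt)) pa else rebuilt
        if (stats::runif(1) < cfg$p_mut) {
          child <- perturb(child, magnitude = cfg$magnitude / 2)
        }
        newpop[[length(newpop) + 1]] <- child
        newfit <- c(newfit, fitness(child))
      }
      pop <- newpop; fit <- newfit
      history[g] <- min(fit)
    }
    ord <- order(fit)
    k <- min(cfg$top_k, cfg$pop)
    structure(list(conformers = pop[ord[seq_len(k)]],
                   chi2 = fit[ord[seq_len(k)]],
                   best_history = history,
                   provenance = list(seed = seed, config = cfg,
                                     generations = cfg$gens)),
              class = "refine_result")
  })
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> best chi2 = %.4g over %d generations\n",
              x$chi2[1], x$provenance$generations))
  invisible(x)
}

#' Write ranked conformers as a multi-model PDB with a chi2 table
#'
#' @param result a [genetic_refine()] result.
#' @param pdb_path multi-model PDB output (protein atoms only).
#' @param table_path optional TSV of per-model chi2.
#' @export
write_conformers <- function(result, pdb_path, table_path = NULL) {
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (m in seq_along(result$conformers)) {
    cf <- result$conformers[[m]]
    cc <- conformer_coords(cf)
    writeLines(sprintf("MODEL     %4d", m), con)
    a <- cf$decomp$atoms
    ele <- ifelse(a$element == "RES", "C", a$element)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(cc$xyz)), a$resid, cc$xyz[, 1], cc$xyz[, 2],
      cc$xyz[, 3], ele), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(table_path)) {
    utils::write.table(
      data.frame(model = seq_along(result$chi2), chi2 = result$chi2),
      table_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(pdb_path)
}
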