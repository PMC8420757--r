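#' Specification for a toy two-domain membrane protein
#'
#' Parameters of the synthetic structures used to exercise the pipeline:
#' a transmembrane helical bundle and a globular soluble domain joined by
#' a flexible bridging linker, mimicking the two-domain architecture of a
#' lipid A phosphoethanolamine transferase (TM bundle + periplasmic
#' soluble domain). All residues are C-alpha-level beads (pseudo-element
#' `"RES"`, one scatterer per residue): full-atom detail contributes
#' nothing at the s-ranges of interest.
#'
#' @param n_tm_helices number of TM helices (bundle).
#' @param tm_length residues per helix.
#' @param soluble_radius radius of the soluble domain, Angstrom.
#' @param linker_length residues in the bridging linker.
#' @param open_distance centroid-centroid distance between TM bundle and
#'   soluble domain in the "open" state, Angstrom.
#' @param seed RNG seed making the generated structure deterministic.
#' @export
toy_protein_spec <- function(n_tm_helices = 4, tm_length = 22,
                             soluble_radius = 14, linker_length = 14,
                             open_distance = 55, seed = 1) {
  stopifnot(n_tm_helices >= 1, tm_length >= 4, soluble_radius > 0,
            linker_length >= 1, open_distance > 0)
  structure(list(n_tm_helices = n_tm_helices, tm_length = tm_length,
                 soluble_radius = soluble_radius,
                 linker_length = linker_length,
                 open_distance = open_distance, seed = seed),
            class = "toy_protein_spec")
}

#' Generate a toy two-domain membrane protein structure
#'
#' Builds a C-alpha bead model: ideal TM helices (1.5 Angstrom rise per
#' residue, 100 degrees per turn step, 2.3 Angstrom helix radius) on a
#' bundle circle, a soluble domain filled with beads on a body-centred
#' grid inside a sphere, and a bridging linker grown bead-by-bead between
#' the two. The `"closed"` and `"open"` states differ only in the
#' placement of the soluble domain: closed sits directly above the bundle,
#' open is displaced to `open_distance` between domain centroids (tilted
#' off-axis). Aromatic-belt marker residues are recorded at the TM
#' boundary planes. Deterministic under the spec's seed.
#'
#' @param spec a [toy_protein_spec()].
#' @param state `"closed"` or `"open"`.
#' @return An object of class `toy_protein`: `atoms` (bead data.frame),
#'   `domains` (residue ranges: `tm`, `linker`, `soluble`), `belt_residues`,
#'   `spec`, `state`.
#' @export
make_toy_protein <- function(spec, state = c("closed", "open")) {
  state <- match.arg(state)
  with_seed(spec$seed, {
    rise <- 1.5; hrad <- 2.3; dphi <- 100 * pi / 180; ca <- 3.8
    nh <- spec$n_tm_helices
    bundle_r <- if (nh == 1) 0 else 9.5 / (2 * sin(pi / nh))
    tm_h <- spec$tm_length * rise
    coords <- list(); resid <- integer(0)
    rid <- 0
    for (h in seq_len(nh)) {
      th0 <- 2 * pi * (h - 1) / nh
      axis_xy <- bundle_r * c(cos(th0), sin(th0))
      zs <- seq(-tm_h / 2, tm_h / 2, length.out = spec$tm_length)
      # antiparallel packing, arranged so the last helix ends at the top
      # (periplasmic) face where the linker to the soluble domain starts
      if ((nh - h) %% 2 == 1) zs <- rev(zs)
      ph <- dphi * seq_len(spec$tm_length) + th0
      coords[[h]] <- cbind(axis_xy[1] + hrad * cos(ph),
                           axis_xy[2] + hrad * sin(ph), zs)
      resid <- c(resid, rid + seq_len(spec$tm_length))
      rid <- rid + spec$tm_length
    }
    tm_xyz <- do.call(rbind, coords)
    n_tm <- nrow(tm_xyz)
    # belt markers: first/last residue of each helix (membrane boundary)
    belt <- resid[abs(abs(tm_xyz[, 3]) - tm_h / 2) < rise / 2]
    # soluble domain: beads on a cubic grid inside a sphere (~133 A^3 each)
    sp <- 133^(1 / 3) * 1.0
    g <- seq(-spec$soluble_radius, spec$soluble_radius, by = sp)
    sol <- as.matrix(expand.grid(g, g, g))
    sol <- sol[rowSums(sol^2) <= spec$soluble_radius^2, , drop = FALSE]
    sol <- sol[order(sol[, 3], sol[, 2], sol[, 1]), , drop = FALSE]
    # place the soluble domain
    tm_top <- tm_h / 2
    closed_ctr <- c(0, 0, tm_top + spec$soluble_radius + 3)
    if (state == "closed") {
      ctr <- closed_ctr
    } else {
      # tilt away from the axis, keeping the centroid distance prescribed
      d <- spec$open_distance
      reach <- ca * (spec$linker_length + 1)
      tilt <- 55 * pi / 180
      ctr <- d * c(sin(tilt), 0, cos(tilt))
    }
    sol_xyz <- sweep(sol, 2, ctr, "+")
    # linker anchors: top of the last helix -> nearest soluble bead
    tm_anchor <- tm_xyz[n_tm, ]   # last TM residue, top face by construction
    d2 <- colSums((t(sol_xyz) - tm_anchor)^2)
    sol_anchor_row <- which.min(d2)
    gap <- sqrt(d2[sol_anchor_row])
    if (gap > ca * (spec$linker_length + 1))
      stop(sprintf(
        "infeasible geometry: linker of %d residues cannot bridge %.1f A",
        spec$linker_length, gap))
    obstacles <- rbind(tm_xyz, sol_xyz)
    link <- grow_bridge(tm_anchor, sol_xyz[sol_anchor_row, ],
                        spec$linker_length, step = ca,
                        obstacles = obstacles)
    if (is.null(link))
      stop("could not grow a clash-free linker for this geometry")
    # order soluble beads starting from the anchor bead
    ord <- order(colSums((t(sol_xyz) - sol_xyz[sol_anchor_row, ])^2))
    sol_xyz <- sol_xyz[ord, , drop = FALSE]
    xyz <- rbind(tm_xyz, link, sol_xyz)
    n <- nrow(xyz)
    atoms <- data.frame(element = "RES", x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], resid = seq_len(n), resname = "ALA",
                        chain = "A", atom_name = "CA",
                        stringsAsFactors = FALSE)
    structure(list(
      atoms = atoms,
      domains = list(tm = c(1, n_tm),
                     linker = c(n_tm + 1, n_tm + spec$linker_length),
                     soluble = c(n_tm + spec$linker_length + 1, n)),
      belt_residues = belt, spec = spec, state = state),
      class = "toy_protein")
  })
}

#' @export
print.toy_protein <- function(x, ...) {
  cat(sprintf("<toy_protein> %s state: %d residues (TM %d-%d, linker %d-%d, soluble %d-%d)\n",
              x$state, nrow(x$atoms), x$domains$tm[1], x$domains$tm[2],
              x$domains$linker[1], x$domains$linker[2],
              x$domains$soluble[1], x$domains$soluble[2]))
  invisible(x)
}

#' Counting-statistics noise model for simulated SAXS frames
#'
#' Sigma follows the Poisson-like form
#' `sigma(s) = sqrt((I(s) + background) / (exposure * incident_scale))`:
#' proportional to the square root of the signal and shrinking with
#' exposure.
#'
#' @param incident_scale incident-flux scale factor (larger = less noise).
#' @param background flat additive background intensity.
#' @export
noise_model <- function(incident_scale = 1000, background = 0.05) {
  stopifnot(incident_scale > 0, background >= 0)
  structure(list(incident_scale = incident_scale, background = background),
            class = "noise_model")
}

#' Simulate a SEC-SAXS frame series
#'
#' Buffer frames carry only the flat background; peak frames add the
#' model's Debye curve scaled by a Gaussian elution envelope. Every point
#' receives Gaussian noise of the noise model's sigma (unless
#' `noisy = FALSE`, which keeps the sigma column but no noise draw -- the
#' noiseless closure used in tests). Ground truth (envelope, scale,
#' model curve) is returned alongside.
#'
#' @param model a [hybrid_model()] of the eluting particle.
#' @param s momentum-transfer grid, inverse Angstrom.
#' @param n_buffer_frames,n_peak_frames frame counts (>= 1).
#' @param noise a [noise_model()].
#' @param peak_scale intensity scale at the envelope maximum.
#' @param exposure seconds per frame.
#' @param buffer_start,peak_start first frame ids of the two blocks.
#' @param noisy draw Gaussian noise (default) or keep exact values.
#' @param seed RNG seed.
#' @return list with `series` (a [frame_series()]) and `truth` (envelope,
#'   per-frame scales, the noiseless model curve, ids).
#' @export
simulate_sec_saxs <- function(model, s = seq(0.008, 0.25, length.out = 120),
                              n_buffer_frames = 20, n_peak_frames = 15,
                              noise = noise_model(), peak_scale = 1,
                              exposure = 5, buffer_start = 100,
                              peak_start = 391, noisy = TRUE, seed = 1) {
  stopifnot(n_buffer_frames >= 1, n_peak_frames >= 1)
  curve <- debye_intensity(model, s)
  I_model <- curve$intensity / curve$intensity[1]   # normalized shape
  env <- exp(-0.5 * ((seq_len(n_peak_frames) - (n_peak_frames + 1) / 2) /
                       (n_peak_frames / 4))^2)
  with_seed(seed, {
    mk <- function(I_true) {
      sig <- sqrt((I_true + noise$background) /
                    (exposure * noise$incident_scale))
      I_obs <- if (noisy) I_true + stats::rnorm(length(s), 0, sig) else I_true
      scattering_profile(s, I_obs + noise$background, sig)
    }
    frames <- c(lapply(seq_len(n_buffer_frames),
                       function(i) mk(rep(0, length(s)))),
                lapply(seq_len(n_peak_frames),
                       function(i) mk(peak_scale * env[i] * I_model)))
    ids <- c(buffer_start + seq_len(n_buffer_frames) - 1,
             peak_start + seq_len(n_peak_frames) - 1)
    list(series = frame_series(frames, frame_ids = ids,
                               exposure = exposure),
         truth = list(s = s, model_curve = I_model, envelope = env,
                      peak_scale = peak_scale,
                      buffer_ids = ids[seq_len(n_buffer_frames)],
                      peak_ids = ids[n_buffer_frames + seq_len(n_peak_frames)],
                      background = noise$background))
  })
}

#' Simulate a tryptophan fluorescence quench titration
#'
#' Gaussian emission spectra on the 315-405 nm grid: KCl (ionic-strength
#' control) wells keep the full amplitude `fmax0`; KI wells are quenched
#' following the Stern-Volmer law `F = fmax0 / (1 + ksv [I-])`, or a
#' two-population mixture `F = fmax0 * sum(w_i / (1 + ksv_i [I-]))` which
#' produces the downward-curved Stern-Volmer plots of heterogeneously
#' shielded fluorophores. Noise is multiplicative per well (CV
#' `noise_cv`) plus a small per-wavelength jitter.
#'
#' @param ksv_true Stern-Volmer constant, 1/M (ignored when `populations`
#'   is given).
#' @param conc_ladder quencher concentrations, M (including 0).
#' @param fmax0 unquenched peak amplitude.
#' @param noise_cv coefficient of variation of the per-well amplitude.
#' @param n_replicates replicate wells per condition.
#' @param lambda_peak,peak_width emission peak centre and Gaussian width, nm.
#' @param populations optional list `list(ksv = c(...), w = c(...))` for
#'   the two-population (curved) regime.
#' @param seed RNG seed.
#' @return list with `ki`, `kcl` (long data.frames: `wavelength`,
#'   `intensity`, `conc`, `replicate`) and `truth`.
#' @export
simulate_quench <- function(ksv_true, conc_ladder = seq(0, 0.5, by = 0.05),
                            fmax0 = 1000, noise_cv = 0.02,
                            n_replicates = 3, lambda_peak = 340,
                            peak_width = 18, populations = NULL,
                            seed = 1) {
  stopifnot(ksv_true >= 0, all(conc_ladder >= 0))
  wl <- 315:405
  shape <- exp(-0.5 * ((wl - lambda_peak) / peak_width)^2)
  qfactor <- function(conc) {
    if (is.null(populations)) 1 / (1 + ksv_true * conc)
    else sum(populations$w / (1 + populations$ksv * conc)) /
      sum(populations$w)
  }
  with_seed(seed, {
    mk <- function(amp) {
      rows <- lapply(seq_len(n_replicates), function(r) {
        well <- amp * (1 + stats::rnorm(1, 0, noise_cv))
        I <- well * shape * (1 + stats::rnorm(length(wl), 0, noise_cv / 5))
        data.frame(wavelength = wl, intensity = I, replicate = r)
      })
      rows
    }
    ki <- kcl <- list()
    for (ci in seq_along(conc_ladder)) {
      conc <- conc_ladder[ci]
      for (df in mk(fmax0 * qfactor(conc))) {
        df$conc <- conc; ki[[length(ki) + 1]] <- df
      }
      for (df in mk(fmax0)) {
        df$conc <- conc; kcl[[length(kcl) + 1]] <- df
      }
    }
    list(ki = do.call(rbind, ki), kcl = do.call(rbind, kcl),
         truth = list(ksv = ksv_true, populations = populations,
                      fmax0 = fmax0, lambda_peak = lambda_peak,
                      noise_cv = noise_cv))
  })
}

#' Write a ground-truth sidecar JSON next to simulated data
#'
#' @param truth list of latent parameters from a simulator.
#' @param path output JSON path.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
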