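#' Dimensionless Kratky transform
#'
#' Computes `(s Rg)^2 I(s) / I0` against `x = s Rg` using Guinier-derived
#' `Rg` and `I0`. Globular particles peak near `(sqrt(3), 1.10)`; extended
#' or flexible particles shift the maximum up and to the right or plateau.
#' The global maximum over `x <= x_max` is located with parabolic
#' interpolation through the three points around the grid maximum.
#'
#' @param profile a [scattering_profile()].
#' @param fit a [guinier_fit()] for the same curve.
#' @param x_max upper `s Rg` bound for the peak search.
#' @return list with `curve` (data.frame `x`, `y`), `peak_x`, `peak_y`.
#' @export
dimensionless_kratky <- function(profile, fit, x_max = 4) {
  x <- profile$s * fit$Rg
  y <- x^2 * profile$intensity / fit$I0
  keep <- x <= x_max
  xx <- x[keep]; yy <- y[keep]
  i <- which.max(yy)
  if (i > 1 && i < length(yy)) {
    # parabola through the three points around the maximum
    x3 <- xx[(i - 1):(i + 1)]; y3 <- yy[(i - 1):(i + 1)]
    d <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
    a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) +
            x3[1] * (y3[3] - y3[2])) / d
    b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) +
            x3[1]^2 * (y3[2] - y3[3])) / d
    c0 <- y3[1] - a * x3[1]^2 - b * x3[1]
    px <- -b / (2 * a)
    py <- a * px^2 + b * px + c0
  } else {
    px <- xx[i]; py <- yy[i]
  }
  list(curve = data.frame(x = x, y = y), peak_x = px, peak_y = py)
}

#' Molecular weight from absolute forward scattering
#'
#' Classical contrast-based estimate
#' `MW = N_A * I0 / (c * drho_M^2)` where the mass-specific contrast is
#' `drho_M = r_e * vbar * (rho_particle - rho_solvent) * 1e24` in cm/g,
#' built from the particle and solvent electron densities (e per cubic
#' Angstrom), the composition-weighted partial specific volume `vbar`
#' (cm^3/g) and the classical electron radius.
#'
#' @param I0_abs forward scattering on absolute scale, 1/cm.
#' @param conc particle concentration, mg/ml.
#' @param vbar partial specific volume, cm^3/g.
#' @param rho_solvent,rho_particle electron densities, e per cubic
#'   Angstrom.
#' @return molecular weight in kDa.
#' @export
mw_from_i0 <- function(I0_abs, conc, vbar, rho_solvent = rho_water,
                       rho_particle) {
  if (conc <= 0) stop("concentration must be positive")
  if (rho_particle == rho_solvent)
    stop("zero contrast: molecular weight undefined")
  r_e <- 2.8179403e-13            # classical electron radius, cm
  N_A <- 6.02214076e23
  drho_m <- r_e * vbar * (rho_particle - rho_solvent) * 1e24  # cm/g
  c_gcm3 <- conc * 1e-3
  mw_da <- N_A * I0_abs / (c_gcm3 * drho_m^2)
  mw_da / 1000
}

#' Conjugate (copolymer) mass decomposition from SEC-MALS
#'
#' Splits a protein:modifier conjugate mass (e.g. a protein:detergent
#' complex) into its protein and modifier components using per-slice
#' protein weight fractions. Fractions can be given directly, or derived
#' from paired UV-derived protein concentrations and refractive-index
#' signals via the two components' dn/dc values: with
#' `ri = c_p * dndc_p + c_m * dndc_m`, the modifier concentration on each
#' slice is `c_m = (ri - c_p * dndc_p) / dndc_m`.
#'
#' @param mw_total conjugate weight-average mass, kDa.
#' @param dn_dc_protein,dn_dc_modifier refractive-index increments, ml/g
#'   (defaults: protein 0.185; see [detergent_defaults] for DDM 0.1608 and
#'   DPC 0.1398).
#' @param fractions per-slice protein weight fractions in `[0, 1]`;
#'   alternatively supply `uv_conc` and `ri_signal`.
#' @param uv_conc per-slice protein concentration from UV absorbance
#'   (mass/volume units consistent with `ri_signal`).
#' @param ri_signal per-slice refractive-index signal in concentration *
#'   dn/dc units.
#' @param monomer_mass modifier monomer mass, Da, for the bound-monomer
#'   count.
#' @return An object of class `conjugate_result`: `mw_total`,
#'   `mw_protein`, `mw_modifier` (kDa), `protein_fraction`, and `n_bound`
#'   (rounded) with `n_bound_exact` kept unrounded.
#' @export
conjugate_decompose <- function(mw_total,
                                dn_dc_protein = dn_dc_protein_default,
                                dn_dc_modifier,
                                fractions = NULL,
                                uv_conc = NULL, ri_signal = NULL,
                                monomer_mass) {
  if (dn_dc_protein <= 0 || dn_dc_modifier <= 0)
    stop("dn/dc values must be positive")
  if (is.null(fractions)) {
    if (is.null(uv_conc) || is.null(ri_signal))
      stop("supply either fractions or uv_conc + ri_signal")
    c_p <- uv_conc
    c_m <- (ri_signal - c_p * dn_dc_protein) / dn_dc_modifier
    fractions <- c_p / (c_p + c_m)
  }
  if (any(fractions < 0 | fractions > 1))
    stop("weight fractions must lie in [0, 1]")
  w <- mean(fractions)
  mw_protein <- w * mw_total
  mw_modifier <- (1 - w) * mw_total
  nb <- bound_detergent_count(mw_total, mw_protein, monomer_mass)
  structure(list(mw_total = mw_total, mw_protein = mw_protein,
                 mw_modifier = mw_modifier, protein_fraction = w,
                 n_bound = nb$n, n_bound_exact = nb$n_exact),
            class = "conjugate_result")
}

#' @export
print.conjugate_result <- function(x, ...) {
  cat(sprintf(
    "<conjugate_result> total %.2f kDa = protein %.2f + modifier %.2f kDa; ~%d bound monomers (%.2f)\n",
    x$mw_total, x$mw_protein, x$mw_modifier, x$n_bound, x$n_bound_exact))
  invisible(x)
}

#' Bound detergent monomers from conjugate masses
#'
#' `(mw_total - mw_protein) * 1000 / monomer_mass`, reported both rounded
#' to the nearest integer and unrounded.
#'
#' @param mw_total,mw_protein conjugate and protein masses, kDa.
#' @param monomer_mass detergent monomer mass, Da.
#' @return list with `n` (rounded) and `n_exact`.
#' @export
bound_detergent_count <- function(mw_total, mw_protein, monomer_mass) {
  if (monomer_mass <= 0) stop("monomer mass must be positive")
  if (mw_total < mw_protein)
    stop("conjugate mass smaller than protein mass")
  n <- (mw_total - mw_protein) * 1000 / monomer_mass
  list(n = as.integer(round(n)), n_exact = n)
}
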