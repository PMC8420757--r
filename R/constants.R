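#' Physical reference tables used across the package
#'
#' Per-element electron counts, displaced solvent volumes and van der Waals
#' radii, plus default detergent and solvent parameters. All values are
#' configuration data: every function that consumes them accepts overrides,
#' none is baked into a formula.
#'
#' The pseudo-element `"RES"` is a residue-level bead used by the toy
#' structure generator: one scatterer per amino-acid residue carrying the
#' electron count and displaced volume of an average residue (about 110 Da).
#'
#' @format `element_table` is a data.frame with columns `element`,
#'   `electrons`, `volume` (displaced solvent volume, cubic Angstrom) and
#'   `vdw` (van der Waals radius, Angstrom). `detergent_defaults` is a named
#'   list with per-detergent tail/head electron densities (e per cubic
#'   Angstrom), monomer masses (Da), dn/dc (ml/g) and tail/head monomer
#'   volumes (cubic Angstrom).
#' @name reference-tables
NULL

#' @rdname reference-tables
#' @export
element_table <- data.frame(
  element   = c("H", "C", "N", "O", "S", "P", "RES"),
  electrons = c(1, 6, 7, 8, 16, 15, 58),
  volume    = c(5.15, 16.44, 2.49, 9.13, 19.86, 5.73, 133.0),
  # RES beads use a carbon-like clash radius: with the 3.8 A virtual bond
  # and the 3.0 A chain-growth avoidance this flags bead contacts < 3.0 A
  vdw       = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.70),
  stringsAsFactors = FALSE
)

#' @rdname reference-tables
#' @export
detergent_defaults <- list(
  DDM = list(rho_tail = 0.277, rho_head = 0.520, monomer_mass = 510.62,
             dn_dc = 0.1608, v_tail = 350, v_head = 505),
  DPC = list(rho_tail = 0.277, rho_head = 0.490, monomer_mass = 351.46,
             dn_dc = 0.1398, v_tail = 350, v_head = 270)
)

#' @rdname reference-tables
#' @export
rho_water <- 0.334

# protein dn/dc, ml/g; standard value for conjugate MALS analysis
#' @rdname reference-tables
#' @export
dn_dc_protein_default <- 0.185
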