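#' Read an atomic structure as a coordinate table
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the flat atom
#' data.frame used throughout the package: one row per atom with columns
#' `element`, `x`, `y`, `z`, `resid` (author residue number), `resname`,
#' `chain`, `atom_name`.
#'
#' @param path PDB file path.
#' @param calpha_only keep only C-alpha atoms.
#' @export
read_structure <- function(path, calpha_only = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (calpha_only) a <- a[a$elety == "CA", , drop = FALSE]
  ele <- toupper(trimws(a$elesy))
  ele[is.na(ele) | ele == ""] <- substr(trimws(a$elety[is.na(ele) | ele == ""]),
                                        1, 1)
  data.frame(element = ele, x = a$x, y = a$y, z = a$z,
             resid = a$resno, resname = a$resid, chain = a$chain,
             atom_name = a$elety, stringsAsFactors = FALSE)
}

#' Write a coordinate table (optionally with a corona) as PDB
#'
#' Protein atoms are written as ATOM records; corona dummy atoms as HETATM
#' on their own chain, with tail points carrying element C and head points
#' element O so the two regions are distinguishable in viewers.
#'
#' @param atoms atom data.frame (as from [read_structure()] or
#'   [make_toy_protein()]), or `NULL`.
#' @param path output file.
#' @param corona optional [build_corona()] result.
#' @export
write_structure <- function(atoms, path, corona = NULL) {
  xyz <- c(); resno <- c(); resid <- c(); chain <- c(); elety <- c()
  elesy <- c(); type <- c()
  if (!is.null(atoms)) {
    xyz <- c(xyz, as.numeric(t(cbind(atoms$x, atoms$y, atoms$z))))
    resno <- c(resno, atoms$resid)
    resid <- c(resid, if (!is.null(atoms$resname)) atoms$resname
               else rep("ALA", nrow(atoms)))
    chain <- c(chain, if (!is.null(atoms$chain)) atoms$chain
               else rep("A", nrow(atoms)))
    nm <- if (!is.null(atoms$atom_name)) atoms$atom_name
          else rep("CA", nrow(atoms))
    elety <- c(elety, nm)
    elesy <- c(elesy, ifelse(atoms$element == "RES", "C", atoms$element))
    type <- c(type, rep("ATOM", nrow(atoms)))
  }
  if (!is.null(corona)) {
    np <- nrow(corona$positions)
    xyz <- c(xyz, as.numeric(t(corona$positions)))
    resno <- c(resno, seq_len(np))
    resid <- c(resid, ifelse(corona$region == "tail", "DTL", "DHD"))
    chain <- c(chain, rep("X", np))
    elety <- c(elety, ifelse(corona$region == "tail", "C", "O"))
    elesy <- c(elesy, ifelse(corona$region == "tail", "C", "O"))
    type <- c(type, rep("HETATM", np))
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = resno, resid = resid, chain = chain,
                   eleno = seq_along(resno), elety = elety, elesy = elesy)
  invisible(path)
}

#' Orient a structure for corona building
#'
#' Rigid rotation + translation placing the membrane normal along +z: the
#' principal axis of the transmembrane atom set is rotated onto z (signed
#' so that any non-TM atoms end up above the TM centroid, matching a
#' periplasmic-facing soluble domain), and the TM centroid is moved to
#' `(0, 0, tm_z_center)`. If aromatic-belt residues are given the
#' orientation is refined so the belt-plane normal (smallest principal
#' component of the belt atoms) is parallel to z.
#'
#' @param atoms atom data.frame.
#' @param tm_residue_ranges list of `c(first, last)` author residue-number
#'   ranges forming the transmembrane segment.
#' @param belt_residues optional residue numbers of the aromatic belt.
#' @param tm_z_center target z of the TM centroid, Angstrom.
#' @return An object of class `oriented_structure`: the transformed
#'   `atoms`, `membrane_normal` (exactly +z), `tm_z_center`, and the
#'   applied `rotation`/`translation`.
#' @export
orient_structure <- function(atoms, tm_residue_ranges, belt_residues = NULL,
                             tm_z_center = 0) {
  if (!length(tm_residue_ranges)) stop("tm_residue_ranges is empty")
  if (!is.list(tm_residue_ranges)) tm_residue_ranges <- list(tm_residue_ranges)
  in_tm <- rep(FALSE, nrow(atoms))
  for (rng in tm_residue_ranges)
    in_tm <- in_tm | (atoms$resid >= rng[1] & atoms$resid <= rng[2])
  if (sum(in_tm) < 3) stop("too few TM atoms to define an axis")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  tm <- xyz[in_tm, , drop = FALSE]
  ctr <- colMeans(tm)
  ev <- eigen(stats::cov(tm), symmetric = TRUE)
  if (ev$values[1] < 1e-8 * max(ev$values[1], 1) || ev$values[1] < 1e-12)
    stop("degenerate TM geometry")
  axis <- ev$vectors[, 1]
  # sign: non-TM centroid (soluble domain) above the TM centroid
  if (any(!in_tm)) {
    sol <- colMeans(xyz[!in_tm, , drop = FALSE]) - ctr
    if (sum(sol * axis) < 0) axis <- -axis
  } else if (axis[3] < 0) axis <- -axis
  R <- rotation_to_z(axis)
  xyz <- sweep(xyz, 2, ctr) %*% t(R)
  if (!is.null(belt_residues)) {
    belt <- xyz[atoms$resid %in% belt_residues, , drop = FALSE]
    if (nrow(belt) >= 3) {
      evb <- eigen(stats::cov(belt), symmetric = TRUE)
      nrm <- evb$vectors[, 3]
      if (nrm[3] < 0) nrm <- -nrm
      Rb <- rotation_to_z(nrm)
      xyz <- xyz %*% t(Rb)
      R <- Rb %*% R
    }
  }
  xyz[, 3] <- xyz[, 3] + tm_z_center
  out <- atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  structure(list(atoms = out, membrane_normal = c(0, 0, 1),
                 tm_z_center = tm_z_center, rotation = R,
                 translation = c(-ctr[1], -ctr[2], tm_z_center - ctr[3]),
                 tm_mask = in_tm),
            class = "oriented_structure")
}

# minimal rotation taking unit vector v onto +z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12)
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  ax <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
          v[1] * z[2] - v[2] * z[1])
  rotation_matrix(ax, acos(c_))
}
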