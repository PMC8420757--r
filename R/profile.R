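#' One-dimensional scattering profile
#'
#' Container for a 1-D SAXS curve: momentum transfer `s` (4 pi sin(theta) /
#' lambda, inverse Angstrom), intensity and 1-sigma uncertainty on a common
#' grid. The `s` grid must be strictly increasing and positive, sigmas
#' strictly positive.
#'
#' @param s numeric, momentum transfer, inverse Angstrom, strictly
#'   increasing, > 0.
#' @param intensity numeric, scattered intensity (arbitrary or absolute
#'   units).
#' @param sigma numeric, 1-sigma uncertainty, same units as `intensity`.
#' @param metadata free-form list recording provenance (file name, frame
#'   range, corrections applied, ...).
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(s, intensity, sigma, metadata = list()) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(s) != length(intensity) || length(s) != length(sigma))
    stop("s, intensity and sigma must have equal length")
  if (any(!is.finite(s)) || any(s <= 0) || any(diff(s) <= 0))
    stop("s must be finite, positive and strictly increasing")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and strictly positive")
  structure(list(s = s, intensity = intensity, sigma = sigma,
                 metadata = metadata),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d points, s = %.4g..%.4g 1/A\n",
              length(x$s), min(x$s), max(x$s)))
  if (length(x$metadata)) {
    lab <- x$metadata$label
    if (!is.null(lab)) cat("  label:", lab, "\n")
  }
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$s) == length(b$s) &&
    all(abs(a$s - b$s) <= tol * pmax(abs(a$s), 1))
}

#' Read / write three-column scattering data
#'
#' Plain whitespace-delimited ASCII with columns s, I, sigma; lines starting
#' with `#` are comments. A missing third column is refused unless
#' `assume_poisson = TRUE`, in which case sigma = sqrt(max(I, eps)) is
#' assigned with a warning.
#'
#' @param path file path.
#' @param assume_poisson logical; tolerate a missing sigma column.
#' @return `read_dat()` returns a [scattering_profile()];
#'   `write_dat()` returns `path` invisibly.
#' @export
read_dat <- function(path, assume_poisson = FALSE) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least two columns (s, I)")
  if (ncol(tab) < 3) {
    if (!assume_poisson)
      stop("no sigma column in ", path,
           "; pass assume_poisson = TRUE to assign sqrt(I) errors")
    warning("assigning sigma = sqrt(max(I, 1e-10))")
    tab$V3 <- sqrt(pmax(tab[[2]], 1e-10))
  }
  scattering_profile(tab[[1]], tab[[2]], tab[[3]],
                     metadata = list(label = basename(path)))
}

#' @param profile a [scattering_profile()].
#' @rdname read_dat
#' @export
write_dat <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lab <- profile$metadata$label
  writeLines(sprintf("# %s", if (is.null(lab)) "scattering profile" else lab),
             con)
  writeLines("#        s              I          sigma", con)
  writeLines(sprintf("%14.8e %14.8e %14.8e",
                     profile$s, profile$intensity, profile$sigma), con)
  invisible(path)
}

#' SEC-SAXS frame series
#'
#' An ordered collection of scattering profiles on one identical s-grid,
#' e.g. successive 5-second exposures across a size-exclusion elution.
#' Frames on even slightly different grids are rejected rather than
#' interpolated, since silent regridding can hide beamline artefacts.
#'
#' @param frames list of [scattering_profile()] objects on one common grid.
#' @param frame_ids integer ids, unique and increasing; defaults to
#'   `seq_along(frames)`.
#' @param exposure seconds per frame.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_ids = seq_along(frames),
                         exposure = 5) {
  if (!length(frames)) stop("empty frame list")
  frame_ids <- as.integer(frame_ids)
  if (anyDuplicated(frame_ids) || any(diff(frame_ids) <= 0))
    stop("frame_ids must be unique and increasing")
  if (length(frame_ids) != length(frames))
    stop("frame_ids and frames lengths differ")
  for (f in frames) {
    if (!inherits(f, "scattering_profile")) stop("frames must be profiles")
    if (!same_grid(f, frames[[1]]))
      stop("all frames must share an identical s-grid (no interpolation)")
  }
  structure(list(frames = frames, frame_ids = frame_ids,
                 exposure = exposure),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames (ids %d..%d), %d s-points, %gs/frame\n",
              length(x$frames), min(x$frame_ids), max(x$frame_ids),
              length(x$frames[[1]]$s), x$exposure))
  invisible(x)
}

#' Read a directory of .dat files as a frame series
#'
#' Files are ordered by the first integer in their file name (falling back
#' to lexicographic order); that integer becomes the frame id.
#'
#' @param dir directory containing `.dat` files, one per frame.
#' @inheritParams frame_series
#' @export
read_frame_dir <- function(dir, exposure = 5) {
  files <- list.files(dir, pattern = "\\.dat$", full.names = TRUE)
  if (!length(files)) stop("no .dat files in ", dir)
  ids <- suppressWarnings(
    as.integer(sub(".*?([0-9]+).*", "\\1", basename(files))))
  if (anyNA(ids) || anyDuplicated(ids)) ids <- seq_along(sort(files))
  ord <- order(ids)
  frame_series(lapply(files[ord], read_dat), frame_ids = ids[ord],
               exposure = exposure)
}
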