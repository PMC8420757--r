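#' Average SEC-SAXS frames
#'
#' Pointwise inverse-variance-weighted mean over the selected frames. The
#' output sigma is the propagated standard error of the weighted mean,
#' `1 / sqrt(sum(1 / sigma_i^2))`, so averaging n identical frames shrinks
#' sigma by `sqrt(n)`.
#'
#' @param series a [frame_series()].
#' @param ids integer frame ids to average (all must be present).
#' @return A [scattering_profile()] with averaging provenance in metadata.
#' @export
average_frames <- function(series, ids) {
  if (!inherits(series, "frame_series")) stop("series must be a frame_series")
  ids <- as.integer(ids)
  if (!length(ids)) stop("empty frame id set")
  idx <- match(ids, series$frame_ids)
  if (anyNA(idx))
    stop("frame id(s) not in series: ",
         paste(ids[is.na(idx)], collapse = ", "))
  I <- vapply(series$frames[idx], `[[`, numeric(length(series$frames[[1]]$s)),
              "intensity")
  S <- vapply(series$frames[idx], `[[`, numeric(length(series$frames[[1]]$s)),
              "sigma")
  if (is.null(dim(I))) { I <- matrix(I, ncol = 1); S <- matrix(S, ncol = 1) }
  w <- 1 / S^2
  wsum <- rowSums(w)
  scattering_profile(
    s = series$frames[[1]]$s,
    intensity = rowSums(I * w) / wsum,
    sigma = 1 / sqrt(wsum),
    metadata = list(label = sprintf("average of frames %d..%d",
                                    min(ids), max(ids)),
                    frames = ids))
}

#' Subtract a buffer profile from a sample profile
#'
#' Pointwise intensity difference with uncertainties added in quadrature.
#' Both profiles must be on the identical s-grid.
#'
#' @param sample,buffer [scattering_profile()] objects on the same grid.
#' @return A [scattering_profile()] of the excess (particle) scattering.
#' @export
subtract_buffer <- function(sample, buffer) {
  if (!same_grid(sample, buffer))
    stop("sample and buffer are on different s-grids")
  scattering_profile(
    s = sample$s,
    intensity = sample$intensity - buffer$intensity,
    sigma = sqrt(sample$sigma^2 + buffer$sigma^2),
    metadata = c(sample$metadata, list(buffer_subtracted = TRUE)))
}

#' Rescale reported uncertainties
#'
#' Some beamline reduction pipelines report 2-standard-error uncertainties;
#' dividing sigma by two restores the standard chi-squared convention. The
#' correction is instrument-specific and therefore always explicit: it is
#' never applied automatically, and the divisor is recorded in metadata.
#'
#' @param profile a [scattering_profile()].
#' @param divisor positive scalar to divide sigma by (2 for a
#'   two-standard-error convention).
#' @export
rescale_errors <- function(profile, divisor) {
  if (!is.numeric(divisor) || length(divisor) != 1 || divisor <= 0)
    stop("divisor must be a positive scalar")
  scattering_profile(profile$s, profile$intensity, profile$sigma / divisor,
                     metadata = c(profile$metadata,
                                  list(sigma_divisor = divisor)))
}

#' Per-frame Guinier trace across an elution peak
#'
#' Runs the automatic Guinier fit on every frame and tabulates Rg and I(0)
#' against frame id, the usual diagnostic for picking sample frames across
#' a SEC-SAXS protein elution peak. Frames where the fit fails yield a row
#' of NA with the failure message rather than aborting the trace.
#'
#' @param series a [frame_series()].
#' @param ... passed to [guinier_fit()] (e.g. `srg_max`).
#' @return data.frame with columns `frame_id`, `Rg`, `I0`, `ok`, `note`.
#' @export
rg_trace <- function(series, ...) {
  rows <- lapply(seq_along(series$frames), function(i) {
    fit <- tryCatch(guinier_fit(series$frames[[i]], ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(frame_id = series$frame_ids[i], Rg = NA_real_,
                 I0 = NA_real_, ok = FALSE, note = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(frame_id = series$frame_ids[i], Rg = fit$Rg, I0 = fit$I0,
                 ok = TRUE, note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
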