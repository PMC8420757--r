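#' Savitzky-Golay smoothing of an emission spectrum
#'
#' Polynomial least-squares convolution smoothing via
#' [signal::sgolayfilt()]. A window of 5 points with quadratic order is
#' the minimum convolution width commonly used on 1-nm-step tryptophan
#' emission spectra; the filter reproduces polynomials up to the chosen
#' order exactly.
#'
#' @param spectrum data.frame with `wavelength` (strictly increasing) and
#'   `intensity` columns.
#' @param window odd window length in points, at least `order + 2`.
#' @param order polynomial order.
#' @return The spectrum with smoothed intensities.
#' @export
smooth_spectrum <- function(spectrum, window = 5, order = 2) {
  check_spectrum(spectrum)
  if (window %% 2 != 1) stop("window must be odd")
  if (window < order + 2) stop("window must be at least order + 2")
  if (window > nrow(spectrum)) stop("window larger than spectrum")
  out <- spectrum
  out$intensity <- signal::sgolayfilt(spectrum$intensity, p = order,
                                      n = window)
  out
}

check_spectrum <- function(spectrum) {
  if (!all(c("wavelength", "intensity") %in% names(spectrum)))
    stop("spectrum needs wavelength and intensity columns")
  if (any(diff(spectrum$wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(spectrum$intensity)))
    stop("non-finite intensities")
  invisible(spectrum)
}

#' Emission maximum wavelength
#'
#' Wavelength of the global intensity maximum. Ties are broken toward the
#' shorter wavelength (the blue-shifted, buried-tryptophan reading) and
#' flagged; a maximum sitting on the grid edge is also flagged since the
#' true peak may lie outside the measured range.
#'
#' @param spectrum data.frame with `wavelength` and `intensity`.
#' @param tol relative tolerance for calling two maxima tied.
#' @return list with `lambda_max` (nm), `tie`, `at_edge`.
#' @export
lambda_max <- function(spectrum, tol = 1e-9) {
  check_spectrum(spectrum)
  I <- spectrum$intensity
  if (diff(range(I)) == 0) stop("flat spectrum: no emission maximum")
  top <- max(I)
  hits <- which(I >= top * (1 - tol) & I >= top - tol * max(abs(top), 1))
  i <- min(hits)
  list(lambda_max = spectrum$wavelength[i],
       tie = length(hits) > 1,
       at_edge = i == 1 || i == length(I))
}

#' Stern-Volmer ratios from matched KI / KCl spectra
#'
#' For each quencher concentration, `F0 / F` is the peak fluorescence of
#' the KCl (ionic-strength control) well divided by the peak fluorescence
#' of the KI well, computed per replicate and then averaged -- the
#' matched-salt construction corrects for ionic strength and dilution,
#' and per-replicate ratios preserve each well's own normalization.
#' Spectra are smoothed ([smooth_spectrum()], window 5) before the peak
#' is read unless `smooth = FALSE`.
#'
#' @param ki_spectra,kcl_spectra long data.frames with columns
#'   `wavelength`, `intensity`, `conc` (quencher concentration, M) and
#'   `replicate`, on matching concentration ladders.
#' @param smooth apply Savitzky-Golay smoothing before peak extraction.
#' @return An object of class `quench_titration`: data.frame with
#'   `conc`, `f_ratio` (mean over replicates), `spread` (sd), `n_rep`.
#' @export
stern_volmer_ratio <- function(ki_spectra, kcl_spectra, smooth = TRUE) {
  for (df in list(ki_spectra, kcl_spectra))
    if (!all(c("wavelength", "intensity", "conc", "replicate") %in%
             names(df)))
      stop("spectra need wavelength, intensity, conc, replicate columns")
  ladder <- sort(unique(ki_spectra$conc))
  if (!identical(ladder, sort(unique(kcl_spectra$conc))))
    stop("KI and KCl concentration ladders do not match")
  peak_of <- function(df) {
    sp <- df[order(df$wavelength), c("wavelength", "intensity")]
    if (smooth && nrow(sp) >= 5) sp <- smooth_spectrum(sp)
    max(sp$intensity)
  }
  rows <- lapply(ladder, function(conc) {
    ki_c <- ki_spectra[ki_spectra$conc == conc, ]
    kcl_c <- kcl_spectra[kcl_spectra$conc == conc, ]
    reps <- sort(unique(ki_c$replicate))
    ratios <- vapply(reps, function(r) {
      fk <- peak_of(ki_c[ki_c$replicate == r, ])
      f0 <- peak_of(kcl_c[kcl_c$replicate == r, ])
      f0 / fk
    }, numeric(1))
    data.frame(conc = conc, f_ratio = mean(ratios),
               spread = if (length(ratios) > 1) stats::sd(ratios) else 0,
               n_rep = length(ratios))
  })
  structure(do.call(rbind, rows), class = c("quench_titration",
                                            "data.frame"))
}

#' Fit the Stern-Volmer constant
#'
#' Fits `F0/F = 1 + KSV [I-]` by least squares with the intercept fixed
#' at 1 (the Stern-Volmer law passes through 1 at zero quencher). If the
#' full-range fit shows lack of linearity -- squared correlation below
#' `r2_min` or a systematic residual trend by a one-sided runs test
#' (p < 0.05, the downward-curvature signature of heterogeneously
#' shielded fluorophores) -- the window shrinks from the
#' high-concentration end until the initial linear region qualifies. A
#' free-intercept diagnostic fit over the same window is reported
#' alongside.
#'
#' @param titration a [stern_volmer_ratio()] result, or any data.frame
#'   with `conc` and `f_ratio` columns (>= 3 points).
#' @param r2_min minimum squared correlation for accepting a window.
#' @return An object of class `ksv_fit`: `ksv` (1/M), `ci95`,
#'   `fitted_range` (largest concentration used), `r_squared`, `n_used`,
#'   `shrunk` flag, and `diagnostic` (free-intercept slope/intercept).
#' @export
fit_ksv <- function(titration, r2_min = 0.95) {
  x_all <- titration$conc; y_all <- titration$f_ratio
  if (length(x_all) < 3) stop("need at least 3 titration points")
  ord <- order(x_all)
  x_all <- x_all[ord]; y_all <- y_all[ord]
  fit_window <- function(n) {
    x <- x_all[seq_len(n)]; y <- y_all[seq_len(n)]
    sxx <- sum(x^2)
    k <- sum(x * (y - 1)) / sxx
    res <- y - (1 + k * x)
    df <- length(x) - 1
    se <- sqrt(sum(res^2) / df / sxx)
    r2 <- if (stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y)^2 else 1
    list(k = k, se = se, df = df, r2 = r2, res = res,
         runs_p = runs_test(res), n = length(x))
  }
  n <- length(x_all)
  shrunk <- FALSE
  repeat {
    f <- fit_window(n)
    if ((f$r2 >= r2_min && f$runs_p >= 0.05) || n <= 3) break
    n <- n - 1
    shrunk <- TRUE
  }
  if (f$r2 < r2_min && f$n <= 3)
    warning("no linear initial window reached r2 >= ", r2_min)
  tq <- stats::qt(0.975, f$df)
  x <- x_all[seq_len(n)]; y <- y_all[seq_len(n)]
  free <- stats::lm(y ~ x)
  structure(list(ksv = f$k, ci95 = f$k + c(-1, 1) * tq * f$se,
                 se = f$se, fitted_range = max(x), r_squared = f$r2,
                 n_used = f$n, shrunk = shrunk,
                 diagnostic = list(slope = unname(stats::coef(free)[2]),
                                   intercept = unname(stats::coef(free)[1]))),
            class = "ksv_fit")
}

#' @export
print.ksv_fit <- function(x, ...) {
  cat(sprintf(
    "<ksv_fit> KSV = %.3f 1/M (95%% CI %.3f-%.3f), %d pts to %.2f M%s, r2 = %.3f\n",
    x$ksv, x$ci95[1], x$ci95[2], x$n_used, x$fitted_range,
    if (x$shrunk) " (window shrunk)" else "", x$r_squared))
  invisible(x)
}
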