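#' Guinier analysis of a scattering profile
#'
#' Weighted linear regression of `ln I` on `s^2` over a low-angle window,
#' giving the radius of gyration `Rg = sqrt(-3 * slope)` and the forward
#' scattering `I0 = exp(intercept)`. Weights are `(I / sigma)^2`, the
#' propagated precision of `ln I`.
#'
#' In automatic mode the window is chosen deterministically: the longest
#' contiguous run of points whose upper limit satisfies `s * Rg <= srg_max`
#' (Rg iterated to self-consistency), skipping at most 5% of the leading
#' points, requiring a linearized correlation of at least `min_corr` and no
#' systematic residual trend (one-sided runs test, p >= 0.05). If no window
#' meets the residual-trend or correlation criteria they are relaxed in that
#' order; the criteria actually met are reported in `fit_quality`.
#'
#' @param profile a [scattering_profile()].
#' @param window optional explicit window `c(s_min, s_max)` in inverse
#'   Angstrom; if `NULL` the automatic selection above is used.
#' @param srg_max upper `s * Rg` limit for the automatic window (1.3, the
#'   usual Guinier validity bound for globular particles).
#' @param min_corr minimum absolute correlation of the linearized fit.
#' @return An object of class `guinier_fit`: `I0`, `Rg` (with standard
#'   errors), the fitted `s_min`/`s_max`, `srg_limits`, `n_points`,
#'   `fit_quality` (correlation, runs-test p, criteria met).
#' @export
guinier_fit <- function(profile, window = NULL, srg_max = 1.3,
                        min_corr = 0.99) {
  s <- profile$s; I <- profile$intensity; sig <- profile$sigma
  if (!is.null(window)) {
    idx <- which(s >= window[1] & s <= window[2])
    if (length(idx) < 5) stop("window contains fewer than 5 points")
    if (any(I[idx] <= 0)) stop("non-positive intensities in Guinier window")
    fit <- guinier_ls(s[idx], I[idx], sig[idx])
    return(guinier_result(fit, s[idx], mode = "explicit",
                          quality = list(corr = fit$corr,
                                         runs_p = runs_test(fit$resid))))
  }
  # automatic mode: iterate Rg on the leading positive-intensity run
  pos <- which(I > 0)
  lead <- pos[seq_len(min(length(pos), 25))]
  if (length(lead) < 5) stop("too few positive low-angle points")
  fit <- guinier_ls(s[lead], I[lead], sig[lead])
  rg <- fit$Rg
  for (iter in 1:25) {
    idx <- which(s * rg <= srg_max & I > 0)
    idx <- idx[idx <= max(pos)]
    if (length(idx) < 5) break
    fit <- guinier_ls(s[idx], I[idx], sig[idx])
    if (abs(fit$Rg - rg) < 1e-6 * rg) { rg <- fit$Rg; break }
    rg <- fit$Rg
  }
  j_max <- max(which(s * rg <= srg_max & I > 0), 5)
  max_skip <- max(1L, ceiling(0.05 * j_max))
  candidates <- list()
  for (i in 1:(max_skip + 1)) {
    j <- j_max
    if (j - i + 1 < 5) next
    sub <- i:j
    if (any(I[sub] <= 0)) next
    f <- try(guinier_ls(s[sub], I[sub], sig[sub]), silent = TRUE)
    if (inherits(f, "try-error")) next
    candidates[[length(candidates) + 1]] <-
      list(fit = f, idx = sub, corr = f$corr, runs_p = runs_test(f$resid))
  }
  if (!length(candidates)) stop("no valid Guinier window found")
  ok_full <- Filter(function(c) c$corr >= min_corr && c$runs_p >= 0.05,
                    candidates)
  ok_corr <- Filter(function(c) c$corr >= min_corr, candidates)
  pool <- if (length(ok_full)) ok_full else
          if (length(ok_corr)) ok_corr else candidates
  met <- if (length(ok_full)) "correlation+runs" else
         if (length(ok_corr)) "correlation" else "none"
  lens <- vapply(pool, function(c) length(c$idx), integer(1))
  best <- pool[[which.max(lens)]]
  guinier_result(best$fit, s[best$idx], mode = "auto",
                 quality = list(corr = best$corr, runs_p = best$runs_p,
                                criteria = met))
}

# weighted least squares of ln I on s^2
guinier_ls <- function(s, I, sig) {
  x <- s^2; y <- log(I); w <- (I / sig)^2
  W <- sum(w); xb <- sum(w * x) / W; yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2); sxy <- sum(w * (x - xb) * (y - yb))
  slope <- sxy / sxx; intercept <- yb - slope * xb
  if (slope >= 0) stop("non-decaying curve: Guinier slope >= 0")
  resid <- y - (intercept + slope * x)
  n <- length(x)
  s2 <- sum(w * resid^2) / max(n - 2, 1)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / W + xb^2 / sxx))
  rg <- sqrt(-3 * slope)
  corr <- abs(sum(w * (x - xb) * (y - yb)) /
                sqrt(sum(w * (x - xb)^2) * sum(w * (y - yb)^2)))
  list(I0 = exp(intercept), Rg = rg,
       I0_err = exp(intercept) * se_int,
       Rg_err = 3 * se_slope / (2 * rg),
       corr = corr, resid = resid, n = n)
}

guinier_result <- function(fit, s_used, mode, quality) {
  structure(list(I0 = fit$I0, Rg = fit$Rg, I0_err = fit$I0_err,
                 Rg_err = fit$Rg_err,
                 s_min = min(s_used), s_max = max(s_used),
                 srg_limits = c(min(s_used), max(s_used)) * fit$Rg,
                 n_points = fit$n, mode = mode, fit_quality = quality),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.2f +/- %.2f A, I0 = %.4g +/- %.2g\n",
              x$Rg, x$Rg_err, x$I0, x$I0_err))
  cat(sprintf("  window %.4g..%.4g 1/A (sRg %.2f..%.2f, %d pts, %s)\n",
              x$s_min, x$s_max, x$srg_limits[1], x$srg_limits[2],
              x$n_points, x$mode))
  invisible(x)
}
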