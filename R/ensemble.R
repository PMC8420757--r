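#' Generate a randomized conformer pool
#'
#' Draws `n_target` conformers by unbiased resampling of the mobile
#' domain's placement -- a uniform random rotation about the bridging
#' anchor plus a random displacement of the domain within the linker's
#' reach -- with the flexible segments rebuilt by self-avoiding chain
#' growth. Conformers clashing with the detergent shell or between bodies
#' (van der Waals overlap beyond `clash_cutoff`) are discarded; the
#' retained fraction is reported. Per-conformer radii of gyration and
#' Debye curves on `s_grid` are precomputed for ensemble selection.
#'
#' @param decomp a [decompose()] result with at least one bridging
#'   segment.
#' @param n_target number of conformers to draw (>= 1).
#' @param clash_cutoff van der Waals overlap cutoff, Angstrom.
#' @param rng_seed RNG seed.
#' @param s_grid momentum-transfer grid for the precomputed curves
#'   (default 51 points over 0-0.12 inverse Angstrom, covering the
#'   low-angle range used for selection).
#' @return An object of class `conformer_pool`: `conformers`, `rg`,
#'   `curves` (length(s_grid) x n matrix), `s`, `n_target`, `retained`.
#' @export
generate_pool <- function(decomp, n_target, clash_cutoff = 0.4,
                          rng_seed = 1,
                          s_grid = seq(0.002, 0.12, length.out = 51)) {
  if (n_target < 1) stop("n_target must be >= 1")
  base <- new_conformer(decomp)
  reach <- 3.8 * (max(vapply(decomp$segments,
                             function(s) length(s$idx), integer(1))) + 1)
  with_seed(rng_seed, {
    keep <- list()
    seg <- decomp$segments[[1]]
    anchor_sep0 <- if (!is.na(seg$anchor_before) && !is.na(seg$anchor_after))
      sqrt(sum((decomp$xyz[seg$anchor_before, ] -
                  decomp$xyz[seg$anchor_after, ])^2)) else 0
    for (i in seq_len(n_target)) {
      # draw until the displaced anchor stays within the linker's reach,
      # then build the chain; only clashing conformers are discarded
      cand <- NULL
      for (draw in 1:20) {
        cand <- base
        cand$rotation <- rotation_matrix(random_unit_vector(),
                                         stats::runif(1, 0, pi))
        tr <- stats::runif(1, 0, 0.8 * reach) * random_unit_vector()
        if (anchor_sep0 + sqrt(sum(tr^2)) > 0.95 * reach) next
        cand$translation <- tr
        cand <- rebuild_linkers(cand)
        if (!is.null(cand)) break
      }
      if (is.null(cand)) next
      if (conformer_clashes(cand, clash_cutoff) > 0) next
      keep[[length(keep) + 1]] <- cand
    }
    if (length(keep) < max(1, 0.01 * n_target))
      stop(sprintf("pool retention below 1%% (%d/%d): geometry too crowded",
                   length(keep), n_target))
    rg <- vapply(keep, function(cf) model_rg(conformer_model(cf)),
                 numeric(1))
    ifun <- conformer_intensity_fun(decomp, s_grid)
    curves <- vapply(keep, ifun, numeric(length(s_grid)))
    structure(list(conformers = keep, rg = rg, curves = curves,
                   s = s_grid, n_target = n_target,
                   retained = length(keep)),
              class = "conformer_pool")
  })
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool> %d/%d conformers retained, Rg %.1f-%.1f A\n",
              x$retained, x$n_target, min(x$rg), max(x$rg)))
  invisible(x)
}

#' Select the sub-ensemble best fitting low-angle data
#'
#' Genetic-algorithm selection in the style of ensemble optimization:
#' chromosomes are fixed-size multisets of pool indices (repetition
#' encodes weights), fitness is the chi-squared of the weighted ensemble
#' curve against the experiment truncated to `s <= s_max_fit`, and the
#' population evolves by tournament selection, uniform crossover,
#' per-slot mutation and elitism. Pool curves are interpolated onto the
#' experimental grid by natural splines. Flexibility of both the selected
#' ensemble and the pool is quantified by [rflex()] over the pool's Rg
#' support.
#'
#' @param pool a [generate_pool()] result.
#' @param experiment experimental [scattering_profile()].
#' @param s_max_fit fit range upper limit, inverse Angstrom (default 0.1,
#'   the overall-shape regime).
#' @param ga_cfg list overriding any of: `n_ens` (20), `pop` (100),
#'   `gens` (150), `tournament` (3), `elitism` (2), `p_mut` (0.1).
#' @param rng_seed RNG seed.
#' @param bins histogram bins for Rg distributions and Rflex.
#' @return An object of class `ensemble_selection`: `indices`, `weights`,
#'   `chi2`, `ensemble_curve`, `rg_selected`, `rg_pool`,
#'   `rg_hist_selected`, `rg_hist_pool`, `rflex_selected`, `rflex_pool`.
#' @export
select_ensemble <- function(pool, experiment, s_max_fit = 0.1,
                            ga_cfg = list(), rng_seed = 1, bins = 50) {
  cfg <- utils::modifyList(list(n_ens = 20, pop = 100, gens = 150,
                                tournament = 3, elitism = 2, p_mut = 0.1),
                           ga_cfg)
  if (pool$retained < 1) stop("empty pool")
  if (pool$retained < 2 && cfg$n_ens > 1)
    stop("pool smaller than a meaningful ensemble")
  keep <- experiment$s <= s_max_fit
  if (sum(keep) < 5) stop("too few experimental points below s_max_fit")
  s_fit <- experiment$s[keep]
  E <- experiment$intensity[keep]; sig <- experiment$sigma[keep]
  # pool curves on the experimental grid
  C <- apply(pool$curves, 2, function(y)
    stats::spline(pool$s, y, xout = s_fit)$y)
  w <- 1 / sig^2
  fitness <- function(chrom) {
    M <- rowMeans(C[, chrom, drop = FALSE])
    sc <- sum(w * M * E) / sum(w * M^2)
    sum(((sc * M - E) / sig)^2) / max(length(E) - 1, 1)
  }
  with_seed(rng_seed, {
    pop <- replicate(cfg$pop,
                     sample.int(pool$retained, cfg$n_ens, replace = TRUE),
                     simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
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
        take <- stats::runif(cfg$n_ens) < 0.5
        child <- ifelse(take, pa, pb)
        mut <- stats::runif(cfg$n_ens) < cfg$p_mut
        if (any(mut)) {
          # half the mutations explore (random pool member), half exploit
          # (duplicate another slot, concentrating weight on good members)
          dup <- stats::runif(sum(mut)) < 0.5
          repl <- integer(sum(mut))
          repl[!dup] <- sample.int(pool$retained, sum(!dup), replace = TRUE)
          repl[dup] <- child[sample.int(cfg$n_ens, sum(dup),
                                        replace = TRUE)]
          child[mut] <- repl
        }
        newpop[[length(newpop) + 1]] <- child
        newfit <- c(newfit, fitness(child))
      }
      pop <- newpop; fit <- newfit
    }
    best <- pop[[which.min(fit)]]
    tab <- table(best)
    idx <- as.integer(names(tab))
    weights <- as.numeric(tab) / cfg$n_ens
    M <- rowMeans(C[, best, drop = FALSE])
    sc <- sum(w * M * E) / sum(w * M^2)
    support <- range(pool$rg)
    structure(list(
      indices = idx, weights = weights, chi2 = min(fit),
      ensemble_curve = scattering_profile(
        s_fit, sc * M, sig, metadata = list(label = "ensemble fit")),
      rg_selected = pool$rg[best], rg_pool = pool$rg,
      rg_hist_selected = rg_histogram(pool$rg[idx], weights, bins, support),
      rg_hist_pool = rg_histogram(pool$rg, NULL, bins, support),
      rflex_selected = rflex(pool$rg[idx], weights, bins = bins,
                             support = support),
      rflex_pool = rflex(pool$rg, bins = bins, support = support),
      provenance = list(seed = rng_seed, config = cfg,
                        s_max_fit = s_max_fit)),
      class = "ensemble_selection")
  })
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf(
    "<ensemble_selection> chi2 = %.4g; Rflex selected %.1f%% vs pool %.1f%%\n",
    x$chi2, x$rflex_selected, x$rflex_pool))
  invisible(x)
}

# weighted histogram over a fixed support
rg_histogram <- function(rg, weights = NULL, bins = 50, support = range(rg)) {
  if (is.null(weights)) weights <- rep(1 / length(rg), length(rg))
  weights <- weights / sum(weights)
  breaks <- seq(support[1], support[2], length.out = bins + 1)
  bin <- findInterval(rg, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- numeric(bins)
  for (i in seq_along(rg)) p[bin[i]] <- p[bin[i]] + weights[i]
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2, p = p)
}

#' Ensemble flexibility metric Rflex
#'
#' `Rflex = 100 * H / H_max`, the Shannon entropy of the (weighted) Rg
#' histogram relative to the maximum-entropy (uniform) histogram,
#' `H_max = log(bins)`. A delta distribution gives 0%; a perfectly
#' uniform histogram gives 100%; a fully random conformer pool
#' approaches 100%. Invariant under affine rescaling of the Rg axis and
#' permutation of the sample.
#'
#' @param rg_values sample of radii of gyration (>= 2 distinct values
#'   unless all mass is a delta).
#' @param weights optional non-negative weights (normalized internally).
#' @param bins histogram bin count (default 50).
#' @param support histogram range; defaults to `range(rg_values)` but
#'   should be the pool's Rg support when comparing a selected ensemble
#'   against its pool.
#' @return flexibility percentage in `[0, 100]`.
#' @export
rflex <- function(rg_values, weights = NULL, bins = 50,
                  support = range(rg_values)) {
  if (!length(rg_values)) stop("empty Rg sample")
  if (support[2] <= support[1]) return(0)
  h <- rg_histogram(rg_values, weights, bins, support)
  p <- h$p[h$p > 0]
  100 * (-sum(p * log(p))) / log(bins)
}
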