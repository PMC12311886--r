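#' Tailored intensity-only noise filter for an MS/MS spectrum
#'
#' Implements the robust-linear-model (RLM) noise filter. The method rests on
#' the observation that uninformative background ions (e.g. electronic noise)
#' have roughly uniformly distributed intensities — so, once the ions of a
#' spectrum are ordered by increasing intensity, the background forms a linear
#' ramp — while true fragment ions are more intense and break away from that
#' trend. The procedure is:
#'
#' 1. order peaks by increasing intensity (ties broken by ascending m/z) and
#'    assign ranks `1..N`;
#' 2. fit a robust linear model `intensity ~ rank` to the lowest
#'    `fit_quantile` share of the ranked ions (ranks `1..ceiling(q*N)`);
#' 3. compute the standard deviation of the RLM residuals over the fitted
#'    subset;
#' 4. draw an upper boundary `k_sd` standard deviations above the trend line;
#' 5. find the ions exceeding their boundary value; if none do, the spectrum
#'    is kept unchanged, otherwise the threshold is the minimum intensity
#'    among the exceeding ions and every peak at or above that intensity is
#'    kept.
#'
#' The cut rule in step 5 keeps the contiguous high-intensity tail starting at
#' the least intense boundary-exceeding ion. An alternative literal reading —
#' cut at the highest-ranked exceeding ion — would discard nearly the whole
#' spectrum and is available as `cut_rule = "last_exceeding"` for comparison.
#'
#' The filter is invariant to uniform intensity rescaling: ranks, the robust
#' fit, the residual spread and the threshold all scale together.
#'
#' @param s A [spectrum].
#' @param fit_quantile Fraction of lowest-intensity ranked ions used for the
#'   fit (default 0.75).
#' @param k_sd Boundary height in residual standard deviations (default 3).
#' @param sd_all If `TRUE`, compute the residual SD over all `N` ranks rather
#'   than the fitted subset (default `FALSE`: residuals of a robust fit are
#'   defined where it was fitted).
#' @param cut_rule `"min_exceeding"` (default) or `"last_exceeding"`, see
#'   Details.
#' @param psi Huber tuning constant for the M-estimator (default 1.345).
#' @return A `denoise_result`; see [denoised()] to extract the filtered
#'   spectrum.
#' @examples
#' lib <- generate_library(synth_config(n_compounds = 2, seed = 7))
#' r <- tailored_denoise(lib[[1]])
#' r
#' denoised(r)
#' @export
tailored_denoise <- function(s, fit_quantile = 0.75, k_sd = 3,
                             sd_all = FALSE,
                             cut_rule = c("min_exceeding", "last_exceeding"),
                             psi = 1.345) {
  validate_spectrum(s)
  cut_rule <- match.arg(cut_rule)
  stopifnot(fit_quantile > 0, fit_quantile <= 1, k_sd > 0)
  n <- n_peaks(s)
  params <- list(fit_quantile = fit_quantile, k_sd = k_sd, sd_all = sd_all,
                 cut_rule = cut_rule)
  if (n < 4) {
    warning("fewer than 4 peaks; spectrum returned unchanged", call. = FALSE)
    return(new_denoise_result(s, rep(TRUE, n), 0, "tailored", params))
  }
  ord <- order(s$intensity, s$mz, method = "radix")
  y <- s$intensity[ord]
  r <- seq_len(n)
  m <- ceiling(fit_quantile * n)
  fit <- tryCatch(
    withCallingHandlers(
      MASS::rlm(y[1:m] ~ r[1:m], psi = MASS::psi.huber, k = psi, maxit = 100),
      warning = function(w) {
        # convergence is checked below via fit$converged
        if (grepl("failed to converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) {
    warning("robust fit failed to converge; falling back to least squares",
            call. = FALSE)
    fit <- stats::lm(y[1:m] ~ r[1:m])
  }
  cf <- stats::coef(fit)
  trend <- cf[1] + cf[2] * r
  sd_res <- if (sd_all) stats::sd(y - trend) else stats::sd(y[1:m] - trend[1:m])
  if (!is.finite(sd_res)) sd_res <- 0
  boundary <- trend + k_sd * sd_res
  exceed <- y > boundary
  if (!any(exceed)) {
    res <- new_denoise_result(s, rep(TRUE, n), 0, "tailored", params)
  } else {
    thr <- if (cut_rule == "min_exceeding") min(y[exceed]) else
      y[max(which(exceed))]
    res <- new_denoise_result(s, s$intensity >= thr, thr, "tailored", params)
  }
  res$fit <- list(order = ord, rank_intensity = y, trend = trend,
                  boundary = boundary, coef = unname(cf), sd = sd_res,
                  n_fit = m)
  res
}

#' Base-peak percentage cutoff filter
#'
#' Removes every ion whose intensity is strictly below `pct` times the base
#' peak (most intense) ion of the spectrum; an ion exactly at the threshold is
#' kept. `pct = 0` is the identity filter.
#'
#' @param s A [spectrum] with at least one peak.
#' @param pct Cutoff as a fraction of base-peak intensity, in `[0, 1]`
#'   (0.05 for a five-percent cutoff).
#' @return A `denoise_result`.
#' @examples
#' s <- spectrum(c(100, 120, 140, 160), c(100, 10, 4, 1), precursor_mz = 200)
#' denoised(percent_cutoff_denoise(s, 0.05))
#' @export
percent_cutoff_denoise <- function(s, pct) {
  validate_spectrum(s)
  if (!is.numeric(pct) || length(pct) != 1 || pct < 0 || pct > 1) {
    stop("pct must be a single value in [0, 1]", call. = FALSE)
  }
  if (!n_peaks(s)) stop("spectrum has no peaks", call. = FALSE)
  thr <- pct * max(s$intensity)
  new_denoise_result(s, s$intensity >= thr, thr, "percent_cutoff",
                     list(pct = pct))
}

#' Consensus spectrum from replicate scans
#'
#' Builds a consensus spectrum from repeated MS/MS acquisitions of the same
#' compound. Peaks are pooled across spectra and grouped by m/z using
#' single-linkage on the sorted pooled values (adjacent peaks closer than
#' `mz_tol` join one group). A group is retained when it contains peaks from
#' at least `min_presence` of the spectra; its consensus m/z is the
#' intensity-weighted mean and its intensity the mean over member peaks.
#' Random background ions appear in few scans and are dropped by the presence
#' requirement.
#'
#' @param spectra At least `min_n` [spectrum] objects of the same polarity
#'   with precursor m/z within `mz_tol` of each other.
#' @param min_presence Minimum fraction of spectra a peak group must appear
#'   in (default 0.7).
#' @param min_n Minimum number of replicate spectra required (default 3).
#' @param mz_tol Grouping tolerance in Da (default 0.01).
#' @return A consensus [spectrum]; its precursor m/z is the mean of the
#'   inputs.
#' @export
consensus_spectrum <- function(spectra, min_presence = 0.7, min_n = 3,
                               mz_tol = 0.01) {
  if (length(spectra) < min_n) {
    stop("consensus requires at least ", min_n, " spectra", call. = FALSE)
  }
  lapply(spectra, validate_spectrum)
  pol <- unique(vapply(spectra, `[[`, "", "polarity"))
  if (length(pol) != 1) stop("mixed polarity", call. = FALSE)
  prec <- vapply(spectra, `[[`, 0, "precursor_mz")
  if (diff(range(prec)) > mz_tol) {
    stop("precursor m/z values differ by more than mz_tol", call. = FALSE)
  }
  ns <- length(spectra)
  mz <- unlist(lapply(spectra, `[[`, "mz"))
  int <- unlist(lapply(spectra, `[[`, "intensity"))
  src <- rep(seq_len(ns), vapply(spectra, n_peaks, 0L))
  ord <- order(mz, method = "radix")
  mz <- mz[ord]; int <- int[ord]; src <- src[ord]
  grp <- cumsum(c(1, diff(mz) > mz_tol))
  presence <- vapply(split(src, grp), function(x) length(unique(x)), 0L)
  keep_grp <- which(presence / ns >= min_presence)
  cons_mz <- vapply(keep_grp, function(g) {
    i <- grp == g
    stats::weighted.mean(mz[i], int[i])
  }, 0)
  cons_int <- vapply(keep_grp, function(g) mean(int[grp == g]), 0)
  spectrum(mz = cons_mz, intensity = cons_int, precursor_mz = mean(prec),
           polarity = pol, id = paste0("consensus_", spectra[[1]]$id),
           metadata = list(n_spectra = ns, method = "consensus",
                           min_presence = min_presence))
}

new_denoise_result <- function(source, keep, threshold, method, params) {
  structure(list(source = source, keep = keep,
                 threshold_intensity = threshold, method = method,
                 params = params),
            class = "denoise_result")
}

#' Extract the denoised spectrum from a filter result
#'
#' @param x A `denoise_result` from [tailored_denoise()] or
#'   [percent_cutoff_denoise()].
#' @return The filtered [spectrum] (a peak subset of the source).
#' @export
denoised <- function(x) {
  stopifnot(inherits(x, "denoise_result"))
  subset_peaks(x$source, x$keep)
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("denoise_result [%s] on '%s': kept %d/%d peaks, threshold %.4g\n",
              x$method, x$source$id, sum(x$keep), length(x$keep),
              x$threshold_intensity))
  invisible(x)
}

#' Plot a tailored denoising result
#'
#' Shows the intensity-ordered ions, the robust trend line fitted to the
#' lowest-intensity ranks and the upper boundary; kept ions are highlighted.
#'
#' @param x A `denoise_result` from [tailored_denoise()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.denoise_result <- function(x, ...) {
  if (is.null(x$fit)) {
    graphics::plot(denoised(x), ...)
    return(invisible(x))
  }
  y <- x$fit$rank_intensity
  r <- seq_along(y)
  kept_ranked <- x$keep[x$fit$order]
  graphics::plot(r, y, pch = 19, cex = 0.6,
                 col = ifelse(kept_ranked, "red", "grey40"),
                 xlab = "intensity rank", ylab = "intensity",
                 main = paste0(x$source$id, " (tailored filter)"), ...)
  graphics::lines(r, x$fit$trend, lty = 2, col = "blue")
  graphics::lines(r, x$fit$boundary, col = "blue")
  invisible(x)
}
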