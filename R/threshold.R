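#' Fraction of explained ions removed by a percentage cutoff
#'
#' Applies [percent_cutoff_denoise()] at `cutoff` to every spectrum and
#' returns the pooled fraction of structurally explained ions that the filter
#' removes (removed explained ions over all spectra, divided by total
#' explained ions). Pooling is ion-weighted, not averaged per spectrum.
#'
#' @param spectra A list of [spectrum] objects, all carrying `explained`
#'   flags.
#' @param cutoff Fraction of base-peak intensity in `[0, 1]`.
#' @return A value in `[0, 1]`; 0 at `cutoff = 0`.
#' @export
explained_removed_fraction <- function(spectra, cutoff) {
  if (any(vapply(spectra, function(s) is.null(s$explained), logical(1)))) {
    stop("all spectra need explained-ion flags", call. = FALSE)
  }
  counts <- vapply(spectra, function(s) {
    keep <- percent_cutoff_denoise(s, cutoff)$keep
    c(removed = sum(s$explained & !keep), total = sum(s$explained))
  }, c(removed = 0, total = 0))
  total <- sum(counts["total", ])
  if (total == 0) stop("no explained ions in the collection", call. = FALSE)
  sum(counts["removed", ]) / total
}

#' Sweep percentage cutoffs and track explained-ion loss vs network collapse
#'
#' For each cutoff the whole collection is denoised, the GNPS similarity
#' matrix and its minimum spanning tree are recomputed, and three summaries
#' are recorded: the pooled fraction of explained ions removed, the network
#' compactness metric `M(d_5%)` ([compute_m_d5()]) and the number of
#' zero-distance (collapsed) tree edges. The tailored filter
#' ([tailored_denoise()]) is run once and its corresponding
#' (explained-removed, `M(d_5%)`) pair is recorded alongside for comparison.
#'
#' @param spectra At least 3 [spectrum] objects with explained flags, one
#'   polarity.
#' @param cutoffs Increasing cutoff grid (default 0 to 0.10 in steps of
#'   0.0025, i.e. 41 points over 0-10%).
#' @param tol Similarity m/z tolerance in Da (default 0.01).
#' @param tailored If `TRUE` (default) also evaluate the tailored filter.
#' @return An object of class `denoise_sweep`: a list with a data frame
#'   `table` (columns `cutoff`, `explained_removed_frac`, `m_d5`,
#'   `zero_count`) and, when requested, `tailored_point` (named vector with
#'   `explained_removed_frac` and `m_d5`).
#' @seealso [optimal_cutoff()]
#' @export
cutoff_sweep <- function(spectra, cutoffs = seq(0, 0.10, by = 0.0025),
                         tol = 0.01, tailored = TRUE) {
  if (length(spectra) < 3) stop("need at least 3 spectra", call. = FALSE)
  stopifnot(length(cutoffs) >= 1, !is.unsorted(cutoffs))
  rows <- lapply(cutoffs, function(ct) {
    den <- lapply(spectra, function(s) denoised(percent_cutoff_denoise(s, ct)))
    tree <- mst(similarity_matrix(den, tol = tol))
    data.frame(cutoff = ct,
               explained_removed_frac = explained_removed_fraction(spectra, ct),
               m_d5 = tree$m_d5, zero_count = tree$zero_count)
  })
  out <- list(table = do.call(rbind, rows), cutoffs = cutoffs, tol = tol)
  if (tailored) {
    res <- lapply(spectra, tailored_denoise)
    den <- lapply(res, denoised)
    tree <- mst(similarity_matrix(den, tol = tol))
    removed <- sum(vapply(res, function(r) sum(r$source$explained & !r$keep), 0))
    total <- sum(vapply(spectra, function(s) sum(s$explained), 0))
    out$tailored_point <- c(explained_removed_frac = removed / total,
                            m_d5 = tree$m_d5)
  }
  structure(out, class = "denoise_sweep")
}

#' @export
print.denoise_sweep <- function(x, ...) {
  tb <- x$table
  cat(sprintf("denoise_sweep over %d cutoffs (%.3g-%.3g)\n",
              nrow(tb), min(tb$cutoff), max(tb$cutoff)))
  cat(sprintf("  M(d_5%%): %.4f -> %.4f; explained removed at max cutoff: %.1f%%\n",
              tb$m_d5[1], tb$m_d5[nrow(tb)],
              100 * tb$explained_removed_frac[nrow(tb)]))
  if (!is.null(x$tailored_point)) {
    cat(sprintf("  tailored filter: %.1f%% explained removed, M(d_5%%) = %.4f\n",
                100 * x$tailored_point["explained_removed_frac"],
                x$tailored_point["m_d5"]))
  }
  invisible(x)
}

#' Plot the two sweep curves and their intersection
#'
#' Draws normalized `M(d_5%)` (network compactness, falling) and the
#' explained-ion removal fraction (information loss, rising) against the
#' cutoff, marking the optimal cutoff and, if present, the tailored-filter
#' operating point.
#'
#' @param x A `denoise_sweep`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.denoise_sweep <- function(x, ...) {
  tb <- x$table
  norm <- tb$m_d5 / tb$m_d5[1]
  graphics::plot(tb$cutoff, norm, type = "b", col = "red", pch = 19,
                 cex = 0.6, ylim = c(0, 1), xlab = "cutoff (fraction of base peak)",
                 ylab = "normalized M(d_5%) / explained ions removed", ...)
  graphics::lines(tb$cutoff, tb$explained_removed_frac, type = "b",
                  col = "blue", pch = 19, cex = 0.6)
  opt <- tryCatch(optimal_cutoff(x), error = function(e) NA_real_)
  if (is.finite(opt)) graphics::abline(v = opt, lty = 2)
  if (!is.null(x$tailored_point)) {
    graphics::points(rep(opt, 0), numeric(0))
    graphics::abline(h = x$tailored_point["explained_removed_frac"],
                     lty = 3, col = "blue")
    graphics::abline(h = x$tailored_point["m_d5"] / tb$m_d5[1],
                     lty = 3, col = "red")
  }
  graphics::legend("right", legend = c("M(d_5%) (normalized)",
                                       "explained ions removed"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Data-dependent optimal noise cutoff
#'
#' The best cutoff balances two contrasting needs: removing the low-intensity
#' ions responsible for false matches while preserving informative fragment
#' ions. `M(d_5%)` is normalized by its value at cutoff 0, so both curves
#' live in `[0, 1]` — one falling from 1 (network tightening/collapse), one
#' rising from 0 (explained-ion loss) — and the grid cutoff closest to their
#' intersection (smallest absolute gap, ties to the smaller cutoff) is
#' returned. With `normalize = "minmax"` the compactness curve is min-max
#' scaled instead.
#'
#' @param r A `denoise_sweep` with at least 3 cutoffs and a nonzero
#'   `M(d_5%)` at cutoff 0.
#' @param normalize `"first"` (default: divide by the cutoff-0 value) or
#'   `"minmax"`.
#' @return The selected cutoff (fraction of base-peak intensity).
#' @export
optimal_cutoff <- function(r, normalize = c("first", "minmax")) {
  stopifnot(inherits(r, "denoise_sweep"))
  normalize <- match.arg(normalize)
  tb <- r$table
  if (nrow(tb) < 3) stop("sweep needs at least 3 cutoffs", call. = FALSE)
  if (tb$m_d5[1] <= 0) {
    stop("network already collapsed at zero cutoff (M(d_5%) = 0)", call. = FALSE)
  }
  norm <- if (normalize == "first") {
    tb$m_d5 / tb$m_d5[1]
  } else {
    rng <- range(tb$m_d5)
    if (diff(rng) == 0) rep(1, nrow(tb)) else (tb$m_d5 - rng[1]) / diff(rng)
  }
  gap <- abs(norm - tb$explained_removed_frac)
  tb$cutoff[which.min(gap)]  # which.min returns the first (smallest) tie
}
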