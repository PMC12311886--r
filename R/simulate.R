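#' Configuration for the synthetic spectrum generator
#'
#' Bundles and validates the generator parameters. The generator emulates the
#' statistical structure that intensity-based denoising relies on: each
#' spectrum is a set of true fragment ions whose intensities clearly exceed a
#' background of uniform-intensity noise ions. Compounds are organized in
#' families that share their dominant "core" fragment m/z values — related
#' compounds share major scaffold ions — while each compound adds its own
#' minor, compound-specific fragments, so similarity networks built from the
#' library have cluster structure.
#'
#' Intensities are relative to the base peak (the largest core ion, fixed at
#' 1): the remaining core ions are uniform on `[0.2, 1]`, compound-specific
#' fragment intensities follow `fragment_intensity_model` (log-normal,
#' defaults meanlog `log(0.06)`, sdlog 0.55), and background ions are uniform
#' on `(0, noise_intensity_max_frac]` of the base peak. The default
#' background ceiling of 1.5% reflects electronic-noise floors one to two
#' orders of magnitude below the base peak, and sits well below the 0-10%
#' cutoff range the sweep explores.
#'
#' @param n_compounds Number of compounds (default 50).
#' @param n_fragments_range Min/max true fragments per spectrum (default
#'   `c(8, 20)`).
#' @param fragment_intensity_model Named numeric vector `c(meanlog, sdlog)`
#'   of the log-normal model for compound-specific relative intensities.
#' @param noise_count_range Min/max background ions per spectrum (default
#'   `c(40, 90)`).
#' @param noise_intensity_max_frac Background intensity ceiling as a
#'   fraction of base peak (default 0.015; ions are uniform on `(0, max]`).
#' @param mz_range Fragment m/z range in Da (default `c(50, 400)`).
#' @param family_count Number of compound families (default 10).
#' @param shared_fragment_frac Fraction of a spectrum's fragments that are
#'   family-shared core ions (default 0.5).
#' @param replicate_count Homologous spectra generated per compound
#'   (default 4; repeated scans across a chromatographic peak).
#' @param replicate_jitter Named numeric vector `c(intensity_cv, mz_sd)`:
#'   multiplicative log-normal intensity scatter between replicates
#'   (coefficient of variation, default 0.15) and Gaussian m/z jitter SD in
#'   Da (default 0.002).
#' @param noise_overlap If `TRUE`, background m/z may fall within
#'   `match_tol` of true fragments; the default `FALSE` keeps noise strictly
#'   unmatchable so planted ground truth is exact.
#' @param match_tol Exclusion tolerance around true peaks in Da
#'   (default 0.01, the similarity tolerance).
#' @param seed Integer RNG seed (default 42).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 50,
                         n_fragments_range = c(8, 20),
                         fragment_intensity_model = c(meanlog = log(0.06),
                                                      sdlog = 0.55),
                         noise_count_range = c(40, 90),
                         noise_intensity_max_frac = 0.015,
                         mz_range = c(50, 400),
                         family_count = 10,
                         shared_fragment_frac = 0.5,
                         replicate_count = 4,
                         replicate_jitter = c(intensity_cv = 0.15,
                                              mz_sd = 0.002),
                         noise_overlap = FALSE,
                         match_tol = 0.01,
                         seed = 42) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_fragments_range = as.integer(n_fragments_range),
              fragment_intensity_model = fragment_intensity_model,
              noise_count_range = as.integer(noise_count_range),
              noise_intensity_max_frac = noise_intensity_max_frac,
              mz_range = mz_range, family_count = as.integer(family_count),
              shared_fragment_frac = shared_fragment_frac,
              replicate_count = as.integer(replicate_count),
              replicate_jitter = replicate_jitter,
              noise_overlap = isTRUE(noise_overlap),
              match_tol = match_tol, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_compounds >= 1, family_count >= 1,
              length(n_fragments_range) == 2,
              n_fragments_range[1] >= 2,
              n_fragments_range[1] <= n_fragments_range[2],
              length(noise_count_range) == 2,
              noise_count_range[1] >= 0,
              noise_count_range[1] <= noise_count_range[2],
              noise_intensity_max_frac > 0, noise_intensity_max_frac <= 1,
              shared_fragment_frac >= 0, shared_fragment_frac <= 1,
              replicate_count >= 1, mz_range[1] < mz_range[2],
              all(replicate_jitter >= 0), match_tol > 0)
  })
  n_core <- round(cfg$shared_fragment_frac * mean(cfg$n_fragments_range))
  if (n_core >= cfg$n_fragments_range[1]) {
    stop("infeasible config: shared core would exceed the minimum fragment count",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  if (has_old) {
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() rm(".Random.seed", envir = globalenv())
  }
}

# m/z values spaced at least `gap` apart, uniform over [lo, hi], avoiding
# `avoid` positions by the same gap
draw_spaced_mz <- function(n, lo, hi, avoid = numeric(), gap = 0.02) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n && tries < 10000) {
    cand <- stats::runif(1, lo, hi)
    if (!length(avoid) || min(abs(cand - avoid)) > gap) {
      avoid <- c(avoid, cand)
      out <- c(out, cand)
    }
    tries <- tries + 1
  }
  if (length(out) < n) stop("could not place spaced m/z values", call. = FALSE)
  out
}

#' Generate a synthetic MS/MS spectrum library with ground-truth labels
#'
#' Produces `n_compounds * replicate_count` spectra according to the model in
#' [synth_config()]. Every peak is labelled: true fragments carry
#' `peak_labels = "fragment"` and `explained = TRUE`, background ions
#' `"noise"` and `FALSE`, so the output doubles as ground truth for filter
#' recovery and for explained-ion loss sweeps. Replicates of a compound share
#' its fragment set, with per-replicate intensity and m/z jitter and freshly
#' drawn background ions; background m/z avoids the neighbourhood of true
#' peaks (see `noise_overlap`), so added background is never matchable by the
#' similarity score. Output is deterministic for a fixed `seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list of [spectrum] objects with ids
#'   `compound<i>_rep<j>` and metadata fields `compound`, `family` and
#'   `replicate`.
#' @examples
#' lib <- generate_library(synth_config(n_compounds = 4, family_count = 2,
#'                                      replicate_count = 2, seed = 1))
#' length(lib)
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  restore <- local_seed(cfg$seed)
  on.exit(restore())
  fam_of <- rep(seq_len(cfg$family_count), length.out = cfg$n_compounds)
  n_core <- round(cfg$shared_fragment_frac * mean(cfg$n_fragments_range))
  mzlo <- cfg$mz_range[1]; mzhi <- cfg$mz_range[2]
  int_sdlog <- sqrt(log(1 + cfg$replicate_jitter[["intensity_cv"]]^2))
  mz_sd <- cfg$replicate_jitter[["mz_sd"]]
  fam <- lapply(seq_len(cfg$family_count), function(f) {
    list(core_mz = sort(draw_spaced_mz(n_core, mzlo, mzhi)),
         core_int = if (n_core == 0) numeric(0) else
           c(1, stats::runif(n_core - 1, 0.2, 1)))
  })
  sample1 <- function(x) x[sample.int(length(x), 1)]
  out <- vector("list", cfg$n_compounds * cfg$replicate_count)
  k <- 0L
  for (ci in seq_len(cfg$n_compounds)) {
    f <- fam[[fam_of[ci]]]
    n_frag <- sample1(seq(cfg$n_fragments_range[1], cfg$n_fragments_range[2]))
    n_spec <- n_frag - n_core
    spec_mz <- draw_spaced_mz(n_spec, mzlo, mzhi, avoid = f$core_mz,
                              gap = 2 * cfg$match_tol)
    spec_int <- pmin(0.95, stats::rlnorm(
      n_spec, cfg$fragment_intensity_model[["meanlog"]],
      cfg$fragment_intensity_model[["sdlog"]]))
    precursor <- stats::runif(1, mzhi + 10, mzhi + 500)
    frag_mz <- c(f$core_mz, spec_mz)
    frag_int <- c(f$core_int, spec_int)
    for (rep_i in seq_len(cfg$replicate_count)) {
      jit_int <- frag_int * stats::rlnorm(n_frag, 0, int_sdlog)
      jit_mz <- frag_mz + stats::rnorm(n_frag, 0, mz_sd)
      base <- max(jit_int)
      n_noise <- sample1(seq(cfg$noise_count_range[1],
                             cfg$noise_count_range[2]))
      noise_mz <- if (n_noise) draw_spaced_mz(
        n_noise, mzlo, precursor - 1,
        avoid = if (cfg$noise_overlap) numeric() else jit_mz,
        gap = cfg$match_tol) else numeric(0)
      noise_int <- stats::runif(n_noise, 0, cfg$noise_intensity_max_frac * base)
      noise_int <- pmax(noise_int, 1e-9 * base)  # open at zero
      k <- k + 1L
      out[[k]] <- spectrum(
        mz = c(jit_mz, noise_mz),
        intensity = c(jit_int, noise_int),
        precursor_mz = precursor, polarity = "positive",
        id = sprintf("compound%03d_rep%d", ci, rep_i),
        peak_labels = c(rep("fragment", n_frag), rep("noise", n_noise)),
        explained = c(rep(TRUE, n_frag), rep(FALSE, n_noise)),
        metadata = list(compound = ci, family = fam_of[ci],
                        replicate = rep_i))
    }
  }
  out
}

#' Add artificial low-intensity noise ions to a spectrum
#'
#' Adds `n` background ions with m/z uniform over `[min(mz), precursor_mz]`
#' — excluding positions within `tol` of existing peaks, so the additions
#' can never match in a similarity comparison — and intensities uniform on
#' `(0, frac * base peak]`. Added peaks are labelled `"noise"` and
#' `explained = FALSE`. Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param s A nonempty [spectrum].
#' @param n Number of ions to add (0 returns the spectrum unchanged).
#' @param frac Intensity ceiling as a fraction of base peak (default 0.05).
#' @param tol Exclusion tolerance in Da around existing peaks (default 0.01).
#' @return The spectrum with `n` extra peaks.
#' @export
add_noise_ions <- function(s, n, frac = 0.05, tol = 0.01) {
  validate_spectrum(s)
  stopifnot(n >= 0, n_peaks(s) >= 1)
  if (n == 0) return(s)
  base <- max(s$intensity)
  mz_new <- draw_spaced_mz(n, min(s$mz), s$precursor_mz, avoid = s$mz,
                           gap = tol)
  int_new <- pmax(stats::runif(n, 0, frac * base), 1e-9 * base)
  if (is.null(s$peak_labels)) s$peak_labels <- rep("unknown", n_peaks(s))
  if (is.null(s$explained)) s$explained <- rep(NA, n_peaks(s))
  spectrum(mz = c(s$mz, mz_new), intensity = c(s$intensity, int_new),
           precursor_mz = s$precursor_mz, polarity = s$polarity, id = s$id,
           peak_labels = c(s$peak_labels, rep("noise", n)),
           explained = c(s$explained, rep(FALSE, n)),
           metadata = s$metadata)
}

#' Configuration for the noise-injection experiment
#'
#' @param increment Step in added-ion count (default 5).
#' @param max_added Maximum ions added (default 100; must be a multiple of
#'   `increment`).
#' @param noise_intensity_frac Intensity ceiling as fraction of base peak
#'   (default 0.05).
#' @param n_simulations Random repetitions per step (default 100).
#' @param seed Integer RNG seed (default 42).
#' @return An object of class `noise_injection_config`.
#' @export
noise_injection_config <- function(increment = 5, max_added = 100,
                                   noise_intensity_frac = 0.05,
                                   n_simulations = 100, seed = 42) {
  stopifnot(increment >= 1, max_added %% increment == 0, n_simulations >= 1,
            noise_intensity_frac > 0)
  structure(list(increment = as.integer(increment),
                 max_added = as.integer(max_added),
                 noise_intensity_frac = noise_intensity_frac,
                 n_simulations = as.integer(n_simulations),
                 seed = as.integer(seed)),
            class = "noise_injection_config")
}

#' Similarity degradation under artificial noise addition
#'
#' Starting from a clean spectrum, repeatedly adds `0, increment, ...,
#' max_added` random low-intensity ions and scores each noisy copy against
#' the clean original with [gnps_score()]. Because the added ions never
#' match, each addition only inflates the scaling denominator, so the mean
#' score declines monotonically with the number of added ions — and declines
#' faster for spectra with fewer fragments, whose score rests on fewer
#' matched peaks.
#'
#' @param clean A [spectrum] with at least one peak.
#' @param cfg A [noise_injection_config()].
#' @param tol Similarity tolerance in Da (default 0.01).
#' @return A list of class `noise_injection` with `summary` (data frame
#'   `n_added`, `mean_score`) and `scores` (matrix of per-simulation scores,
#'   simulations in rows, one column per `n_added` step).
#' @export
noise_injection_experiment <- function(clean, cfg = noise_injection_config(),
                                       tol = 0.01) {
  validate_spectrum(clean)
  stopifnot(inherits(cfg, "noise_injection_config"), n_peaks(clean) >= 1)
  restore <- local_seed(cfg$seed)
  on.exit(restore())
  n_added <- seq(0, cfg$max_added, by = cfg$increment)
  scores <- matrix(NA_real_, nrow = cfg$n_simulations, ncol = length(n_added),
                   dimnames = list(NULL, n_added))
  for (sim in seq_len(cfg$n_simulations)) {
    for (ci in seq_along(n_added)) {
      noisy <- add_noise_ions(clean, n_added[ci],
                              frac = cfg$noise_intensity_frac, tol = tol)
      scores[sim, ci] <- gnps_score(clean, noisy, tol = tol)
    }
  }
  structure(list(summary = data.frame(n_added = n_added,
                                      mean_score = colMeans(scores)),
                 scores = scores),
            class = "noise_injection")
}

#' @export
print.noise_injection <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("noise_injection: %d simulations, %d steps; mean score ",
                     "%.3f at n=%d -> %.3f at n=%d\n"),
              nrow(x$scores), nrow(s), s$mean_score[1], s$n_added[1],
              s$mean_score[nrow(s)], s$n_added[nrow(s)]))
  invisible(x)
}

#' Plot similarity decline under noise injection
#'
#' Gray lines are individual simulations; the bold line is the mean score
#' per added-ion count.
#'
#' @param x A `noise_injection` result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.noise_injection <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$n_added, s$mean_score, type = "n", ylim = c(0, 1),
                 xlab = "added noise ions", ylab = "GNPS score", ...)
  for (i in seq_len(nrow(x$scores))) {
    graphics::lines(s$n_added, x$scores[i, ], col = "grey85")
  }
  graphics::lines(s$n_added, s$mean_score, lwd = 2)
  invisible(x)
}
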