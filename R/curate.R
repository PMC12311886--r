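#' Library-curation filter for MS/MS spectra
#'
#' Applies the standard quality filters used when assembling spectral
#' libraries: spectra are retained when their spectral entropy is strictly
#' below `max_entropy` (noisy spectra have flat, high-entropy intensity
#' distributions), their peak count is strictly above `min_ions` and strictly
#' below `max_ions`, and — when explained-ion flags are available — the ratio
#' of explained ions to total ions is strictly below `max_explained_ratio`
#' (a higher ratio suggests the spectrum was already denoised or manually
#' curated). All comparisons are strict.
#'
#' @param spectra A list of [spectrum] objects.
#' @param max_entropy Entropy bound (default 3, natural log units).
#' @param min_ions Exclusive lower peak-count bound (default 20).
#' @param max_ions Exclusive upper peak-count bound (default 1000).
#' @param max_explained_ratio Exclusive bound on explained/total ions
#'   (default 0.75). Skipped with a warning for spectra lacking flags.
#' @return The retained spectra, in input order (possibly empty).
#' @examples
#' lib <- generate_library(synth_config(n_compounds = 3, seed = 1))
#' length(curate(lib))
#' @export
curate <- function(spectra, max_entropy = 3, min_ions = 20, max_ions = 1000,
                   max_explained_ratio = 0.75) {
  stopifnot(max_entropy > 0, min_ions > 0, max_ions > 0, min_ions < max_ions,
            max_explained_ratio > 0)
  missing_flags <- FALSE
  keep <- vapply(spectra, function(s) {
    n <- n_peaks(s)
    ok <- n > min_ions && n < max_ions && spectral_entropy(s) < max_entropy
    if (ok) {
      if (is.null(s$explained)) {
        missing_flags <<- TRUE
      } else {
        ok <- sum(s$explained) / n < max_explained_ratio
      }
    }
    ok
  }, logical(1))
  if (missing_flags) {
    warning("explained-ion flags absent for some spectra; ",
            "explained-ratio filter skipped for those", call. = FALSE)
  }
  spectra[keep]
}
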