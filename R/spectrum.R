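#' Construct an MS/MS spectrum object
#'
#' A `spectrum` holds one tandem-MS scan: the precursor m/z, the ionization
#' polarity and parallel peak arrays (fragment m/z and intensity), optionally
#' annotated with per-peak labels and explained-ion flags.
#'
#' Peaks are stored sorted by ascending m/z; exact duplicate m/z values are
#' merged by summing their intensities (parsers in the wild emit duplicates,
#' and downstream code relies on strictly increasing m/z).
#'
#' @param mz Numeric vector of fragment m/z values (Da).
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param precursor_mz Precursor m/z (Da), a single positive number.
#' @param polarity `"positive"` or `"negative"`.
#' @param id Spectrum identifier (any string).
#' @param peak_labels Optional character vector, one of `"fragment"`,
#'   `"noise"`, `"unknown"` per peak.
#' @param explained Optional logical vector flagging structurally explainable
#'   fragment ions (e.g. exported from a fragmentation-tree tool).
#' @param metadata Optional named list of free-form metadata (compound name,
#'   adduct, collision energy, ...).
#'
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(mz = c(81.03, 109.03, 163.04), intensity = c(10, 40, 100),
#'               precursor_mz = 181.05, polarity = "negative", id = "ex1")
#' s
#' spectral_entropy(s)
#' @export
spectrum <- function(mz, intensity, precursor_mz, polarity = "positive",
                     id = "spectrum", peak_labels = NULL, explained = NULL,
                     metadata = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  ord <- order(mz, method = "radix")
  mz <- mz[ord]; intensity <- intensity[ord]
  if (!is.null(peak_labels)) peak_labels <- as.character(peak_labels)[ord]
  if (!is.null(explained)) explained <- as.logical(explained)[ord]
  # merge exact duplicate m/z by summing intensity
  if (anyDuplicated(mz)) {
    grp <- match(mz, mz)
    keep <- !duplicated(mz)
    # rowsum orders by group key (= first occurrence index), preserving mz order
    intensity <- unname(rowsum(intensity, grp)[, 1])
    if (!is.null(peak_labels)) peak_labels <- peak_labels[keep]
    if (!is.null(explained)) explained <- explained[keep]
    mz <- mz[keep]
    message("merged duplicate m/z values in spectrum '", id, "'")
  }
  s <- structure(
    list(id = as.character(id), precursor_mz = as.numeric(precursor_mz),
         polarity = match.arg(polarity, c("positive", "negative")),
         mz = mz, intensity = intensity,
         peak_labels = peak_labels, explained = explained,
         metadata = metadata),
    class = "spectrum")
  validate_spectrum(s)
  s
}

#' Validate a spectrum object
#'
#' Checks the structural invariants: equal-length peak arrays, strictly
#' increasing m/z, non-negative intensities, positive precursor m/z and
#' length-matched optional annotations.
#'
#' @param s A `spectrum`.
#' @return `s`, invisibly; errors if any invariant fails.
#' @export
validate_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$mz)
  if (length(s$intensity) != n) stop("mz/intensity length mismatch", call. = FALSE)
  if (n > 1 && any(diff(s$mz) <= 0)) stop("mz must be strictly increasing", call. = FALSE)
  if (any(!is.finite(s$mz)) || any(!is.finite(s$intensity))) {
    stop("non-finite peak values", call. = FALSE)
  }
  if (any(s$intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.finite(s$precursor_mz) || s$precursor_mz <= 0) {
    stop("precursor_mz must be positive", call. = FALSE)
  }
  if (!s$polarity %in% c("positive", "negative")) stop("invalid polarity", call. = FALSE)
  if (!is.null(s$peak_labels) && length(s$peak_labels) != n) {
    stop("peak_labels length mismatch", call. = FALSE)
  }
  if (!is.null(s$explained) && length(s$explained) != n) {
    stop("explained length mismatch", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum '%s': %d peaks, precursor m/z %.4f [%s]\n",
              x$id, length(x$mz), x$precursor_mz, x$polarity))
  if (length(x$mz)) {
    cat(sprintf("  m/z %.4f-%.4f, base peak %.4f (intensity %.4g)\n",
                min(x$mz), max(x$mz), x$mz[which.max(x$intensity)],
                max(x$intensity)))
  }
  if (!is.null(x$explained)) {
    cat(sprintf("  explained ions: %d/%d\n", sum(x$explained), length(x$mz)))
  }
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "h",
                 xlab = "m/z", ylab = "intensity",
                 main = x$id, ...)
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s A `spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(s) length(s$mz)

#' Subset the peaks of a spectrum
#'
#' Returns a copy of the spectrum retaining only the peaks selected by `keep`,
#' subsetting any per-peak annotations alongside.
#'
#' @param s A `spectrum`.
#' @param keep Logical or integer index over peaks.
#' @return A `spectrum` with the selected peaks.
#' @export
subset_peaks <- function(s, keep) {
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  if (!is.null(s$peak_labels)) s$peak_labels <- s$peak_labels[keep]
  if (!is.null(s$explained)) s$explained <- s$explained[keep]
  validate_spectrum(s)
}

#' Shannon spectral entropy
#'
#' Entropy of the peak intensities normalized to sum one, using the natural
#' logarithm: \eqn{-\sum_i p_i \log p_i}. High entropy marks flat, noisy
#' intensity distributions; spectral-library curation commonly discards
#' spectra with entropy of 3 or more as poor quality.
#'
#' @param s A `spectrum` with at least one non-zero intensity.
#' @return Non-negative entropy value (nats).
#' @examples
#' s <- spectrum(c(100, 200), c(1, 1), precursor_mz = 300)
#' spectral_entropy(s)  # log(2)
#' @export
spectral_entropy <- function(s) {
  validate_spectrum(s)
  tot <- sum(s$intensity)
  if (tot <= 0) stop("spectral entropy undefined for all-zero intensities", call. = FALSE)
  p <- s$intensity / tot
  p <- p[p > 0]
  -sum(p * log(p))
}
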