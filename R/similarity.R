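#' Candidate peak pairs between two spectra (direct and neutral-loss)
#'
#' Enumerates every candidate peak pair used by the GNPS-style modified
#' cosine: a *direct* pair matches on absolute m/z
#' (`|mzA - mzB| <= tol`), a *shifted* pair matches after shifting by the
#' precursor difference (`|(mzA - mzB) - (precA - precB)| <= tol`), i.e. the
#' two fragments share a neutral loss. A pair qualifying both ways is counted
#' once (as direct). A peak may occur in several candidate pairs; the
#' one-to-one assignment happens in [gnps_score()].
#'
#' The weight of a pair is the product of the two peaks' square-root
#' transformed, unit-norm-scaled intensities (or raw intensities with
#' `transform = "raw"`).
#'
#' @param a,b [spectrum] objects with positive precursor m/z.
#' @param tol Absolute m/z tolerance in Da (default 0.01).
#' @param transform Intensity transform before normalization: `"sqrt"`
#'   (default, standard GNPS scaling) or `"raw"`.
#' @return An object of class `peak_match_set`: a data frame with columns
#'   `i` (peak index in `a`), `j` (peak index in `b`), `kind`
#'   (`"direct"`/`"shifted"`) and `weight`, plus attributes `tolerance` and
#'   the two norm-scaled intensity vectors.
#' @export
join_peaks_gnps <- function(a, b, tol = 0.01, transform = c("sqrt", "raw")) {
  validate_spectrum(a); validate_spectrum(b)
  transform <- match.arg(transform)
  if (!n_peaks(a) || !n_peaks(b)) {
    stop("both spectra must be nonempty", call. = FALSE)
  }
  wa <- scaled_intensity(a$intensity, transform)
  wb <- scaled_intensity(b$intensity, transform)
  d <- outer(a$mz, b$mz, "-")
  direct <- which(abs(d) <= tol, arr.ind = TRUE)
  shifted <- which(abs(d - (a$precursor_mz - b$precursor_mz)) <= tol,
                   arr.ind = TRUE)
  pairs <- rbind(
    if (nrow(direct)) data.frame(i = direct[, 1], j = direct[, 2],
                                 kind = "direct"),
    if (nrow(shifted)) data.frame(i = shifted[, 1], j = shifted[, 2],
                                  kind = "shifted"))
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(), kind = character())
  }
  dup <- duplicated(pairs[c("i", "j")])  # direct rows come first
  pairs <- pairs[!dup, , drop = FALSE]
  pairs$weight <- wa[pairs$i] * wb[pairs$j]
  structure(pairs, class = c("peak_match_set", "data.frame"),
            tolerance = tol, wa = wa, wb = wb)
}

scaled_intensity <- function(intensity, transform) {
  w <- if (transform == "sqrt") sqrt(intensity) else intensity
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w / nrm else w
}

#' GNPS-style modified-cosine similarity between two spectra
#'
#' Square-root transforms each spectrum's intensities and scales them to unit
#' Euclidean norm, enumerates candidate peak pairs matching directly or by
#' neutral loss ([join_peaks_gnps()]), and selects a one-to-one assignment —
#' each peak of either spectrum used at most once — greedily by descending
#' pair weight. Weight ties are broken by ascending m/z of the first, then
#' second, spectrum's peak, which makes the selection symmetric in the
#' argument order. The score is the sum of selected pair weights, clamped to
#' `[0, 1]`; identical spectra score exactly 1 and spectra with no candidate
#' pairs score 0.
#'
#' Because each spectrum's scaling denominator includes *all* of its peaks,
#' adding peaks that match nothing strictly lowers the score — the mechanism
#' by which low-intensity noise degrades spectral matching.
#'
#' @inheritParams join_peaks_gnps
#' @param assignment `"greedy"` (default, mirrors the reference scoring) or
#'   `"optimal"` (exact maximum-weight assignment by branch and bound;
#'   intended for small spectra and validation).
#' @return Similarity in `[0, 1]`.
#' @examples
#' a <- spectrum(c(81.03, 109.03, 163.04), c(20, 40, 100), precursor_mz = 181.05)
#' gnps_score(a, a)
#' @export
gnps_score <- function(a, b, tol = 0.01, transform = c("sqrt", "raw"),
                       assignment = c("greedy", "optimal")) {
  assignment <- match.arg(assignment)
  transform <- match.arg(transform)
  if (!n_peaks(a) || !n_peaks(b)) {
    warning("empty spectrum; score is 0", call. = FALSE)
    return(0)
  }
  pm <- join_peaks_gnps(a, b, tol = tol, transform = transform)
  if (!nrow(pm)) return(0)
  total <- if (assignment == "greedy") {
    greedy_assignment_weight(pm$i, pm$j, pm$weight, a$mz[pm$i], b$mz[pm$j])
  } else {
    optimal_assignment_weight(pm$i, pm$j, pm$weight)
  }
  min(1, max(0, total))
}

greedy_assignment_weight <- function(i, j, w, mzi, mzj) {
  ord <- order(-w, mzi, mzj, method = "radix")
  used_i <- logical(max(i)); used_j <- logical(max(j))
  total <- 0
  for (k in ord) {
    if (!used_i[i[k]] && !used_j[j[k]]) {
      used_i[i[k]] <- TRUE; used_j[j[k]] <- TRUE
      total <- total + w[k]
    }
  }
  total
}

optimal_assignment_weight <- function(i, j, w) {
  ord <- order(-w)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  n <- length(w)
  suffix <- rev(cumsum(rev(w)))
  best <- 0
  recurse <- function(k, used_i, used_j, acc) {
    if (acc > best) best <<- acc
    if (k > n || acc + suffix[k] <= best) return()
    # take pair k if possible
    if (!i[k] %in% used_i && !j[k] %in% used_j) {
      recurse(k + 1, c(used_i, i[k]), c(used_j, j[k]), acc + w[k])
    }
    recurse(k + 1, used_i, used_j, acc)
  }
  recurse(1, integer(), integer(), 0)
  best
}

#' Normalized sum of low-intensity ion signal
#'
#' Sums the base-peak-normalized intensities of every ion strictly below
#' `frac` of the base peak. Across repeated scans of one compound this
#' quantity tracks how much presumed noise a spectrum carries, and it
#' correlates negatively with the similarity score between homologous
#' spectra.
#'
#' @param s A nonempty [spectrum].
#' @param frac Low-intensity bound as a fraction of base peak (default 0.05).
#' @return Non-negative sum (invariant to uniform intensity rescaling).
#' @export
low_intensity_sum <- function(s, frac = 0.05) {
  validate_spectrum(s)
  if (!n_peaks(s)) stop("spectrum has no peaks", call. = FALSE)
  base <- max(s$intensity)
  if (base <= 0) return(0)
  low <- s$intensity < frac * base
  sum(s$intensity[low]) / base
}
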