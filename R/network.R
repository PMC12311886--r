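#' Pairwise GNPS similarity matrix over a spectrum collection
#'
#' Computes [gnps_score()] for every spectrum pair. Molecular networks are
#' built per ionization mode, so mixing polarities is an error. The diagonal
#' is forced to exactly 1.
#'
#' @param spectra A list of [spectrum] objects of one polarity with unique
#'   ids.
#' @param tol m/z tolerance in Da (default 0.01).
#' @param ... Passed to [gnps_score()].
#' @return A `similarity_matrix`: a symmetric numeric matrix with unit
#'   diagonal and spectrum ids as dimnames.
#' @export
similarity_matrix <- function(spectra, tol = 0.01, ...) {
  n <- length(spectra)
  if (!n) stop("no spectra", call. = FALSE)
  if (length(unique(vapply(spectra, `[[`, "", "polarity"))) > 1) {
    stop("mixed polarity: build one network per ionization mode", call. = FALSE)
  }
  ids <- vapply(spectra, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("spectrum ids must be unique", call. = FALSE)
  S <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        S[i, j] <- S[j, i] <- gnps_score(spectra[[i]], spectra[[j]],
                                         tol = tol, ...)
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d spectra, %d strictly positive pairs\n",
              nrow(x), sum(x[upper.tri(x)] > 0)))
  print(unclass(x), ...)
  invisible(x)
}

check_simmat <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (is.null(rownames(M))) {
    dimnames(M) <- list(as.character(seq_len(nrow(M))),
                        as.character(seq_len(nrow(M))))
  }
  if (max(abs(M - t(M))) > 1e-8) stop("matrix not symmetric", call. = FALSE)
  if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
    stop("similarities must lie in [0, 1]", call. = FALSE)
  }
  M
}

#' Molecular-network edge list
#'
#' Returns all unordered spectrum pairs with similarity strictly above
#' `threshold`. The default threshold 0 is the zero-thresholding approach:
#' every strictly positive similarity becomes an edge, avoiding bias from an
#' arbitrary cutoff choice.
#'
#' @param M A [similarity_matrix()] (or any symmetric similarity matrix with
#'   ids as dimnames).
#' @param threshold Minimum similarity, exclusive (default 0).
#' @return A data frame with columns `id_i`, `id_j`, `score`.
#' @export
network_edges <- function(M, threshold = 0) {
  M <- check_simmat(M)
  ids <- rownames(M)
  idx <- which(upper.tri(M) & M > threshold, arr.ind = TRUE)
  data.frame(id_i = ids[idx[, 1]], id_j = ids[idx[, 2]],
             score = M[idx], stringsAsFactors = FALSE)
}

#' Minimum spanning tree of the molecular network
#'
#' Converts similarities to distances `d = 1 - s` on the *complete* graph
#' (so the tree spans every spectrum, including pairs of zero similarity at
#' distance 1) and computes the minimum spanning tree by Kruskal's algorithm
#' with deterministic tie-breaking (lexicographic on the id pair). The sorted
#' distribution of the n-1 tree distances summarizes the network structure:
#' a slide of the low end toward zero signals that denoising is collapsing
#' distinct compounds into indistinguishable spectra.
#'
#' @param M A [similarity_matrix()] over at least two spectra.
#' @return An object of class `mst_result` with elements `edges` (data frame
#'   `id_i`, `id_j`, `distance`), `sorted_distances`, `zero_count` (distances
#'   below 1e-12, i.e. exact collapse), `m_d5` (see [compute_m_d5()]) and
#'   `ids`.
#' @export
mst <- function(M) {
  M <- check_simmat(M)
  n <- nrow(M)
  if (n < 2) stop("need at least 2 spectra for a spanning tree", call. = FALSE)
  ids <- rownames(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  d <- 1 - M[ut]
  ei <- ut[, 1]; ej <- ut[, 2]
  ord <- order(d, ids[ei], ids[ej], method = "radix")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- integer(n - 1)
  k <- 0L
  for (e in ord) {
    ri <- find(ei[e]); rj <- find(ej[e])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      take[k] <- e
      if (k == n - 1L) break
    }
  }
  edges <- data.frame(id_i = ids[ei[take]], id_j = ids[ej[take]],
                      distance = d[take], stringsAsFactors = FALSE)
  sorted <- sort(edges$distance)
  structure(list(edges = edges, sorted_distances = sorted,
                 zero_count = sum(sorted < 1e-12),
                 m_d5 = compute_m_d5(sorted), ids = ids),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf(paste0("mst_result: %d nodes, %d edges, total weight %.4f\n",
                     "  zero distances: %d; M(d_5%%) = %.4f\n"),
              length(x$ids), nrow(x$edges), sum(x$edges$distance),
              x$zero_count, x$m_d5))
  invisible(x)
}

#' Median of the lowest fifth percentile of MST distances
#'
#' `M(d_5%)` takes the `ceiling(0.05 * length)` smallest distances and
#' returns their median (midpoint convention for even counts). As this value
#' approaches zero a significant portion (5%) of the network has collapsed:
#' an important fraction of spectra have become mutually indistinguishable.
#'
#' @param sorted_distances Nondecreasing numeric vector of MST edge
#'   distances.
#' @return The median of the lowest-5% subset.
#' @examples
#' compute_m_d5(0.01 * (1:100))  # lowest five are 0.01..0.05 -> 0.03
#' @export
compute_m_d5 <- function(sorted_distances) {
  n <- length(sorted_distances)
  if (!n) stop("empty distance vector", call. = FALSE)
  if (is.unsorted(sorted_distances)) {
    stop("distances must be nondecreasing", call. = FALSE)
  }
  k <- ceiling(0.05 * n)
  stats::median(sorted_distances[seq_len(k)])
}

#' Ordered MST distance curves for plotting
#'
#' Stacks the sorted MST distance sequences of several networks (e.g. raw
#' data and a series of denoising cutoffs) into one long-format table.
#' Distances are also reported as square roots, which spreads out the
#' low-magnitude differences near zero where network collapse shows.
#'
#' @param results Named list of `mst_result` objects over the same spectrum
#'   set.
#' @return A data frame with columns `label`, `rank`, `distance`,
#'   `sqrt_distance`.
#' @export
ordered_distance_curve <- function(results) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  node_sets <- lapply(results, function(r) sort(r$ids))
  if (length(unique(node_sets)) != 1) {
    stop("all results must cover the same spectrum set", call. = FALSE)
  }
  do.call(rbind, lapply(names(results), function(lbl) {
    d <- results[[lbl]]$sorted_distances
    data.frame(label = lbl, rank = seq_along(d), distance = d,
               sqrt_distance = sqrt(d), stringsAsFactors = FALSE)
  }))
}
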