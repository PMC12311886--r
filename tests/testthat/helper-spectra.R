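# Test helpers: quick spectrum builders and independent brute-force oracles.
# The oracles deliberately re-derive results from first principles and do not
# call the package's own matching/tree code paths.

make_spec <- function(mz, intensity, precursor = 500, polarity = "positive",
                      id = "s", ...) {
  spectrum(mz = mz, intensity = intensity, precursor_mz = precursor,
           polarity = polarity, id = id, ...)
}

# random spectrum with peaks spaced > 0.2 Da so tolerance matching is unambiguous
random_spectrum <- function(n = 8, id = "r", precursor = NULL) {
  mz <- 50 + cumsum(runif(n, 0.5, 15))
  if (is.null(precursor)) precursor <- max(mz) + runif(1, 20, 200)
  make_spec(mz, rlnorm(n, 0, 1), precursor = precursor, id = id)
}

# m/z positions guaranteed unmatchable against spectrum `a` given precursors
unmatchable_mz <- function(a, prec_b, n, tol = 0.01) {
  shift <- a$precursor_mz - prec_b
  bad <- c(a$mz, a$mz - shift)
  out <- numeric(0)
  x <- 41.7
  while (length(out) < n) {
    if (min(abs(x - bad)) > 5 * tol) out <- c(out, x)
    x <- x + 1.37
  }
  out
}

# Exact maximum-weight one-to-one assignment score, by plain recursion over
# all candidate pairs (direct or neutral-loss matched, sqrt/unit-norm scaled).
bf_gnps_optimal <- function(a, b, tol = 0.01) {
  wa <- sqrt(a$intensity) / sqrt(sum(a$intensity))
  wb <- sqrt(b$intensity) / sqrt(sum(b$intensity))
  shift <- a$precursor_mz - b$precursor_mz
  pairs <- list()
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      if (abs(a$mz[i] - b$mz[j]) <= tol ||
          abs((a$mz[i] - b$mz[j]) - shift) <= tol) {
        pairs[[length(pairs) + 1]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (!length(pairs)) return(0)
  best <- 0
  recurse <- function(k, used_i, used_j, acc) {
    if (acc > best) best <<- acc
    if (k > length(pairs)) return()
    p <- pairs[[k]]
    if (!p[1] %in% used_i && !p[2] %in% used_j) {
      recurse(k + 1, c(used_i, p[1]), c(used_j, p[2]), acc + p[3])
    }
    recurse(k + 1, used_i, used_j, acc)
  }
  recurse(1, integer(), integer(), 0)
  min(1, best)
}

# Minimum spanning-tree weight by exhaustive enumeration of all edge subsets
# of size n-1 that span the graph (connectivity via union-find).
bf_mst_weight <- function(D) {
  n <- nrow(D)
  pairs <- utils::combn(n, 2)
  w <- D[t(pairs)]
  m <- ncol(pairs)
  subsets <- utils::combn(m, n - 1)
  best <- Inf
  for (col in seq_len(ncol(subsets))) {
    sel <- subsets[, col]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    comp <- n
    for (e in sel) {
      ri <- find(pairs[1, e]); rj <- find(pairs[2, e])
      if (ri != rj) { parent[ri] <- rj; comp <- comp - 1 }
    }
    if (comp == 1) best <- min(best, sum(w[sel]))
  }
  best
}

# Literal transcription of the tailored filter's five steps, kept separate
# from the package implementation.
tailored_oracle_keep <- function(s, q = 0.75, k_sd = 3) {
  n <- length(s$mz)
  ord <- order(s$intensity, s$mz)
  y <- s$intensity[ord]
  m <- ceiling(q * n)
  fit <- MASS::rlm(y[seq_len(m)] ~ seq_len(m), maxit = 100)
  a <- coef(fit)[1]; b <- coef(fit)[2]
  res_sd <- sd(y[seq_len(m)] - (a + b * seq_len(m)))
  bound <- a + b * seq_len(n) + k_sd * res_sd
  exceed <- y > bound
  if (!any(exceed)) return(rep(TRUE, n))
  thr <- min(y[exceed])
  s$intensity >= thr
}

# a small random similarity matrix with exact unit diagonal
random_simmat <- function(n, ids = sprintf("n%02d", seq_len(n)), ties = FALSE) {
  vals <- if (ties) sample(seq(0, 1, by = 0.25), n * (n - 1) / 2, TRUE) else
    runif(n * (n - 1) / 2)
  S <- diag(1, n)
  S[upper.tri(S)] <- vals
  S <- pmax(S, t(S))
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}
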