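test_that("similarity matrix has unit diagonal and matches direct recomputation", {
  set.seed(53)
  one <- similarity_matrix(list(random_spectrum(5, id = "only")))
  expect_equal(unclass(one), matrix(1, 1, 1, dimnames = list("only", "only")))
  s <- random_spectrum(8, id = "a")
  dup <- s; dup$id <- "b"
  M <- similarity_matrix(list(s, dup))
  expect_equal(M["a", "b"], 1)  # duplicate spectrum scores 1 off-diagonal
  lib <- lapply(1:6, function(i) random_spectrum(sample(6:12, 1),
                                                 id = paste0("s", i)))
  M <- similarity_matrix(lib)
  expect_equal(unclass(M), t(unclass(M)))
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 1 else gnps_score(lib[[i]], lib[[j]])
    expect_equal(M[i, j], expected)
  }
  bad <- lib
  bad[[2]]$polarity <- "negative"
  expect_error(similarity_matrix(bad), "polarity")
})

test_that("zero-threshold edges keep every strictly positive similarity", {
  S <- diag(1, 3)
  dimnames(S) <- list(letters[1:3], letters[1:3])
  expect_equal(nrow(network_edges(S)), 0)
  S["a", "b"] <- S["b", "a"] <- 0.8
  S["a", "c"] <- S["c", "a"] <- 0.69
  S["b", "c"] <- S["c", "b"] <- 0.71
  expect_equal(nrow(network_edges(S, 0.70)), 2)  # the common 0.70 MN threshold
  expect_equal(nrow(network_edges(S)), 3)
  set.seed(59)
  S <- random_simmat(7)
  S[S < 0.3 & S != 1] <- 0
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  ed <- network_edges(S, 0.25)
  count <- 0
  for (i in 1:6) for (j in (i + 1):7) if (S[i, j] > 0.25) count <- count + 1
  expect_equal(nrow(ed), count)
})

test_that("three-node MST picks the two shortest distances", {
  S <- matrix(c(1, 0.9, 0.5, 0.9, 1, 0.2, 0.5, 0.2, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- mst(S)
  expect_equal(sort(tr$edges$distance), c(0.1, 0.5))
  expect_equal(sum(tr$edges$distance), 0.6)
  got <- apply(tr$edges[c("id_i", "id_j")], 1, paste, collapse = "")
  expect_setequal(got, c("AB", "AC"))
})

test_that("Kruskal matches exhaustive spanning-tree enumeration and igraph", {
  set.seed(61)
  for (case in 1:50) {
    n <- sample(3:7, 1)
    S <- random_simmat(n)
    tr <- mst(S)
    expect_equal(nrow(tr$edges), n - 1)
    w <- sum(tr$edges$distance)
    expect_equal(w, bf_mst_weight(1 - S))
    g <- igraph::graph_from_adjacency_matrix(1 - S, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g, algorithm = "prim")
    expect_equal(w, sum(igraph::E(ig)$weight))
  }
})

test_that("sorted MST distances are invariant under node permutation despite ties", {
  set.seed(67)
  for (case in 1:10) {
    n <- sample(4:8, 1)
    S <- random_simmat(n, ties = TRUE)
    ref <- mst(S)$sorted_distances
    for (p in 1:3) {
      perm <- sample(n)
      expect_equal(mst(S[perm, perm])$sorted_distances, ref)
    }
  }
})

test_that("MST spans all nodes acyclically", {
  set.seed(71)
  S <- random_simmat(12)
  tr <- mst(S)
  expect_equal(nrow(tr$edges), 11)
  # n-1 edges touching all n nodes => a tree
  expect_setequal(unique(c(tr$edges$id_i, tr$edges$id_j)), rownames(S))
})

test_that("M(d_5%) matches the quantile-subset-median oracle", {
  expect_equal(compute_m_d5(0.01 * (1:100)), 0.03)
  expect_equal(compute_m_d5(rep(0.4, 37)), 0.4)
  set.seed(73)
  for (case in 1:20) {
    d <- sort(runif(sample(2:200, 1)))
    expect_equal(compute_m_d5(d), median(d[seq_len(ceiling(0.05 * length(d)))]))
    expect_gte(compute_m_d5(d), min(d))
    expect_lte(compute_m_d5(d), median(d))
  }
  expect_error(compute_m_d5(numeric(0)), "empty")
  expect_error(compute_m_d5(c(0.5, 0.1)), "nondecreasing")
})

test_that("ordered distance curves stack results in long format", {
  set.seed(79)
  S <- random_simmat(3)
  r1 <- mst(S)
  tab <- ordered_distance_curve(list(raw = r1))
  expect_equal(nrow(tab), 2)
  r2 <- mst(S^2)  # same nodes, different distances
  tab <- ordered_distance_curve(list(raw = r1, cut = r2))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$sqrt_distance, sqrt(tab$distance))
  r3 <- mst(random_simmat(4))
  expect_error(ordered_distance_curve(list(a = r1, b = r3)), "same spectrum set")
})
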