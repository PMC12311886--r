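test_that("explained-ion removal fraction matches hand counting", {
  mk <- function(int, expl, id) {
    make_spec(seq(100, by = 5, length.out = length(int)), int,
              explained = expl, id = id)
  }
  # identity cutoff removes nothing
  s <- mk(c(100, 10, 1), c(TRUE, TRUE, FALSE), "a")
  expect_equal(explained_removed_fraction(list(s), 0), 0)
  # all explained ions below the cutoff
  s2 <- mk(c(100, 2, 1), c(FALSE, TRUE, TRUE), "b")
  expect_equal(explained_removed_fraction(list(s2), 0.05), 1)
  # constructed 10-spectrum set with known flags vs a hand count
  set.seed(83)
  pool <- lapply(1:10, function(i) {
    n <- sample(5:15, 1)
    mk(c(100, runif(n - 1, 0, 20)), sample(c(TRUE, FALSE), n, TRUE),
       paste0("s", i))
  })
  cutoff <- 0.07
  removed <- total <- 0
  for (s in pool) {
    thr <- cutoff * max(s$intensity)
    removed <- removed + sum(s$explained & s$intensity < thr)
    total <- total + sum(s$explained)
  }
  expect_equal(explained_removed_fraction(pool, cutoff), removed / total)
  expect_error(explained_removed_fraction(list(mk(1:3, rep(FALSE, 3), "z")), 0.1),
               "no explained ions")
  s_noflag <- make_spec(c(100, 200), c(1, 2))
  expect_error(explained_removed_fraction(list(s_noflag), 0.1), "flags")
})

test_that("optimal cutoff finds curve intersections on the grid", {
  mk_sweep <- function(cutoffs, m_d5, expl) {
    structure(list(table = data.frame(cutoff = cutoffs,
                                      explained_removed_frac = expl,
                                      m_d5 = m_d5,
                                      zero_count = 0L),
                   cutoffs = cutoffs, tol = 0.01),
              class = "denoise_sweep")
  }
  # curves crossing exactly at a grid point
  cutoffs <- seq(0, 0.1, by = 0.01)
  sw <- mk_sweep(cutoffs, m_d5 = seq(1, 0, length.out = 11),
                 expl = seq(0, 1, length.out = 11))
  expect_equal(optimal_cutoff(sw), 0.05)
  # linear curves with an off-grid analytic crossing:
  # normalized m_d5 = 1 - 8*c, explained = 4*c -> cross at c = 1/12 = 0.0833,
  # nearest grid point 0.08
  sw <- mk_sweep(cutoffs, m_d5 = pmax(0, 1 - 8 * cutoffs), expl = 4 * cutoffs)
  expect_equal(optimal_cutoff(sw), 0.08)
  # flat compactness and zero removal everywhere -> tie broken to cutoff 0
  sw <- mk_sweep(cutoffs, m_d5 = rep(0.4, 11), expl = rep(0, 11))
  expect_equal(optimal_cutoff(sw), 0)
  # collapsed network at cutoff zero is an error
  sw <- mk_sweep(cutoffs, m_d5 = rep(0, 11), expl = seq(0, 1, length.out = 11))
  expect_error(optimal_cutoff(sw), "collapsed")
  sw <- mk_sweep(cutoffs[1:2], m_d5 = c(1, 0.5), expl = c(0, 0.5))
  expect_error(optimal_cutoff(sw), "at least 3")
})

test_that("a single-point sweep reproduces the raw-data network metrics", {
  lib <- generate_library(synth_config(n_compounds = 6, family_count = 2,
                                       replicate_count = 1,
                                       noise_count_range = c(10, 20), seed = 15))
  sw <- cutoff_sweep(lib, cutoffs = 0, tailored = FALSE)
  expect_equal(nrow(sw$table), 1)
  expect_equal(sw$table$explained_removed_frac, 0)
  raw_tree <- mst(similarity_matrix(lib))
  expect_equal(sw$table$m_d5, raw_tree$m_d5)
  expect_equal(sw$table$zero_count, raw_tree$zero_count)
})

test_that("optimal cutoff is invariant to uniform intensity rescaling", {
  lib <- generate_library(synth_config(n_compounds = 8, family_count = 2,
                                       replicate_count = 1,
                                       noise_count_range = c(15, 30), seed = 16))
  cuts <- seq(0, 0.1, by = 0.02)
  sw1 <- cutoff_sweep(lib, cutoffs = cuts, tailored = FALSE)
  scaled <- lapply(lib, function(s) { s$intensity <- s$intensity * 250; s })
  sw2 <- cutoff_sweep(scaled, cutoffs = cuts, tailored = FALSE)
  expect_equal(sw2$table, sw1$table)
  expect_equal(optimal_cutoff(sw2), optimal_cutoff(sw1))
})
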