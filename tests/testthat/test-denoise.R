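test_that("equal-intensity spectra pass through the tailored filter unchanged", {
  s <- make_spec(seq(100, by = 7, length.out = 20), rep(4.2, 20))
  r <- suppressWarnings(tailored_denoise(s))
  expect_true(all(r$keep))
  expect_equal(r$threshold_intensity, 0)
  expect_equal(denoised(r)$mz, s$mz)
})

test_that("planted fragments over an exactly linear background are recovered", {
  set.seed(7)
  n_bg <- 90
  bg_mz <- sort(runif(n_bg, 50, 400))
  frag_mz <- sort(runif(10, 401, 480))
  # background whose sorted intensities lie exactly on a slope-1 line
  s <- make_spec(c(bg_mz, frag_mz), c(seq_len(n_bg), rep(50 * n_bg, 10)),
                 precursor = 500)
  # zero-residual data stalls the M-estimator's scale step; the documented
  # least-squares fallback gives the identical line
  expect_warning(r <- tailored_denoise(s), "least squares")
  expect_identical(r$keep, s$intensity == 50 * n_bg)
  expect_equal(r$threshold_intensity, 50 * n_bg)
  # direct boundary computation: no background ion exceeds its own rank value
  expect_true(all(sort(s$intensity)[1:n_bg] <= seq_len(n_bg) + 1e-9))
})

test_that("tailored filter agrees with a step-by-step oracle on hockey-stick spectra", {
  set.seed(19)
  for (case in 1:10) {
    n_bg <- sample(40:120, 1)
    n_fr <- sample(6:18, 1)
    mz <- 50 + cumsum(runif(n_bg + n_fr, 0.5, 4))
    int <- c(runif(n_bg, 0, 0.02), pmin(1, rlnorm(n_fr, log(0.2), 0.8)))
    s <- make_spec(mz, int, precursor = max(mz) + 50)
    expect_identical(tailored_denoise(s)$keep, tailored_oracle_keep(s))
  }
})

test_that("tailored filter is invariant to uniform intensity rescaling", {
  set.seed(23)
  lib <- generate_library(synth_config(n_compounds = 3, family_count = 1,
                                       replicate_count = 1, seed = 4))
  for (s in lib) {
    r1 <- tailored_denoise(s)
    s2 <- s; s2$intensity <- s2$intensity * 1e5
    r2 <- tailored_denoise(s2)
    expect_identical(r1$keep, r2$keep)
    expect_equal(r2$threshold_intensity, r1$threshold_intensity * 1e5)
  }
})

test_that("tiny spectra are returned unchanged with a warning", {
  s <- make_spec(c(100, 110, 120), c(1, 5, 9))
  expect_warning(r <- tailored_denoise(s), "fewer than 4")
  expect_true(all(r$keep))
})

test_that("percentage cutoff removes strictly-below ions only", {
  s <- make_spec(c(100, 120, 140, 160), c(100, 10, 4, 1))
  r <- percent_cutoff_denoise(s, 0.05)
  expect_equal(r$threshold_intensity, 5)
  expect_equal(denoised(r)$intensity, c(100, 10))
  # pct = 0 is the identity
  expect_true(all(percent_cutoff_denoise(s, 0)$keep))
  # a peak exactly at the threshold is kept
  s2 <- make_spec(c(100, 120), c(100, 5))
  expect_true(all(percent_cutoff_denoise(s2, 0.05)$keep))
  expect_error(percent_cutoff_denoise(s, 1.5), "\\[0, 1\\]")
})

test_that("cutoff keep-sets are nested and the base peak survives every filter", {
  set.seed(31)
  for (rep in 1:5) {
    s <- random_spectrum(40)
    pcts <- sort(runif(4, 0, 1))
    keeps <- lapply(pcts, function(p) percent_cutoff_denoise(s, p)$keep)
    for (k in seq_len(length(keeps) - 1)) {
      expect_true(all(keeps[[k + 1]] <= keeps[[k]]))  # keep(pct2) subset of keep(pct1)
    }
    base_idx <- which.max(s$intensity)
    expect_true(keeps[[length(keeps)]][base_idx])
    expect_true(tailored_denoise(s)$keep[base_idx])
  }
})

test_that("denoised output peaks are a subset of the source peaks", {
  set.seed(37)
  s <- random_spectrum(60)
  for (r in list(tailored_denoise(s), percent_cutoff_denoise(s, 0.07))) {
    d <- denoised(r)
    expect_true(all(d$mz %in% s$mz))
    expect_true(all(d$intensity %in% s$intensity))
    expect_true(all(d$intensity >= r$threshold_intensity))
  }
})

test_that("consensus of identical replicates reproduces the input", {
  s <- make_spec(c(100.1, 150.2, 200.3), c(5, 50, 20), precursor = 300)
  cons <- consensus_spectrum(list(s, s, s))
  expect_equal(cons$mz, s$mz)
  expect_equal(cons$intensity, s$intensity)
  expect_equal(cons$precursor_mz, s$precursor_mz)
})

test_that("consensus drops peaks under the presence threshold", {
  s1 <- make_spec(c(100.1, 150.2), c(10, 20), precursor = 300)
  s2 <- make_spec(c(100.1, 150.2), c(12, 18), precursor = 300)
  s3 <- make_spec(c(150.2, 250.9), c(22, 5), precursor = 300)
  cons <- consensus_spectrum(list(s1, s2, s3))
  # 100.1 present in 2/3 (66.7% < 70%) -> dropped; 150.2 in 3/3 -> kept
  expect_equal(cons$mz, 150.2)
  expect_equal(cons$intensity, 20)
})

test_that("consensus retention matches brute-force presence counting", {
  set.seed(41)
  base_mz <- seq(100, 400, by = 25)
  specs <- lapply(1:5, function(i) {
    present <- runif(length(base_mz)) < 0.6
    if (!any(present)) present[1] <- TRUE
    make_spec(base_mz[present] + runif(sum(present), -0.003, 0.003),
              rlnorm(sum(present)), precursor = 500, id = paste0("r", i))
  })
  cons <- consensus_spectrum(specs, min_presence = 0.7, mz_tol = 0.01)
  counts <- vapply(base_mz, function(m) {
    sum(vapply(specs, function(s) any(abs(s$mz - m) < 0.01), logical(1)))
  }, 0L)
  expect_equal(length(cons$mz), sum(counts / 5 >= 0.7))
  expect_true(all(vapply(cons$mz, function(m) min(abs(base_mz - m)) < 0.01,
                         logical(1))))
})

test_that("consensus preconditions are enforced", {
  s <- make_spec(c(100, 200), c(1, 2), precursor = 300)
  expect_error(consensus_spectrum(list(s, s)), "at least 3")
  s_neg <- make_spec(c(100, 200), c(1, 2), precursor = 300, polarity = "negative")
  expect_error(consensus_spectrum(list(s, s, s_neg)), "polarity")
  s_far <- make_spec(c(100, 200), c(1, 2), precursor = 310)
  expect_error(consensus_spectrum(list(s, s, s_far)), "precursor")
})
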