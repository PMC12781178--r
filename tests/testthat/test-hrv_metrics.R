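test_that("mean_rr averages valid intervals only", {
  expect_equal(mean_rr(rr_series(rep(800, 3))), 800)
  s <- rr_series(c(700, 2500, 900), valid = c(TRUE, FALSE, TRUE))
  expect_equal(mean_rr(s), 800)
  expect_equal(mean_rr(gen_rr("white", 200, 800, 0, seed = 1)), 800)
  none <- rr_series(c(800, 810), valid = FALSE)
  expect_error(mean_rr(none), class = "hrvrisk_no_valid_rr")
})

test_that("sample entropy matches its definition on structured inputs", {
  per2 <- rep(c(800, 850), 100)
  expect_equal(sample_entropy(per2, m = 2), 0)
  x <- withr::with_seed(20, rnorm(400))
  expect_lte(sample_entropy(x, 2, 0.3), sample_entropy(x, 2, 0.1))
  expect_error(sample_entropy(rnorm(50)), class = "hrvrisk_too_few_points")
})

test_that("sample and fuzzy entropy agree with brute-force oracles", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(300, 800, 50))
    expect_equal(sample_entropy(x, 2, 0.15), oracle_sampen(x, 2, 0.15),
                 tolerance = 1e-10)
    expect_equal(fuzzy_entropy(x, 2, 0.15, 2), oracle_fuzzyen(x, 2, 0.15, 2),
                 tolerance = 1e-10)
  }
})

test_that("fuzzy entropy limits: constant series and saturating tolerance", {
  expect_equal(fuzzy_entropy(rep(800, 200)), 0)
  x <- withr::with_seed(21, rnorm(300))
  expect_lt(abs(fuzzy_entropy(x, 2, 100)), 1e-3)
})

test_that("multiscale entropy: scale-1 identity, noise decay, short-series NA", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed + 40, rnorm(600, 800, 40))
    mse <- multiscale_entropy(x, max_scale = 5)
    expect_identical(mse$curve$sample_entropy[1], sample_entropy(x))
  }
  dec <- purrr::map_lgl(1:10, function(seed) {
    x <- withr::with_seed(seed + 60, rnorm(1200))
    m <- multiscale_entropy(x, max_scale = 5)
    m$curve$sample_entropy[5] < m$curve$sample_entropy[1]
  })
  expect_true(all(dec))

  short <- withr::with_seed(3, rnorm(220, 800, 40))
  m <- multiscale_entropy(short, max_scale = 10)
  expect_true(all(is.na(m$curve$sample_entropy[5:10])))  # < 50 points
  expect_equal(m$summary,
               mean(m$curve$sample_entropy[is.finite(m$curve$sample_entropy)]))
})

test_that("DFA alpha1 hits the analytic limits and flags constants", {
  aw <- mean(purrr::map_dbl(1:10, function(s) {
    dfa_alpha1(withr::with_seed(s, rnorm(4096)))
  }))
  expect_gt(aw, 0.44); expect_lt(aw, 0.56)
  ap <- mean(purrr::map_dbl(1:10, function(s) {
    dfa_alpha1(gen_rr("pink", 4096, 800, 40, seed = s))
  }))
  expect_gt(ap, 0.88); expect_lt(ap, 1.12)
  expect_true(is.na(dfa_alpha1(rep(800, 500))))
  expect_error(dfa_alpha1(rnorm(150)), class = "hrvrisk_too_few_points")
})

test_that("power-law fit recovers spectral slopes and enforces duration", {
  white_slopes <- purrr::map_dbl(1:8, function(s) {
    powerlaw_fit(gen_rr("white", 2000, 800, 40, seed = s))$slope
  })
  expect_lt(abs(mean(white_slopes)), 0.15)

  pink <- purrr::map(1:8, function(s) {
    powerlaw_fit(gen_rr("pink", 2000, 800, 40, seed = s))
  })
  expect_lt(abs(mean(purrr::map_dbl(pink, "slope")) + 1), 0.2)
  expect_gt(mean(purrr::map_dbl(pink, "r2")), 0.85)

  five_min <- gen_rr("white", 370, 800, 30, seed = 1)
  expect_error(powerlaw_fit(five_min), class = "hrvrisk_too_short")
})

test_that("Porta index: symmetry, reversal antisymmetry, ramp convention", {
  alt <- rr_series(c(rep(c(800, 850), 100), 800))  # even pair count
  expect_equal(asymmetry_index(alt), 50.0)

  ramp <- rr_series(seq(700, 900, length.out = 150))
  expect_equal(asymmetry_index(ramp), 0.0)

  for (seed in 1:20) {
    s <- gen_rr("white", 300, 800, 40, seed = seed + 100)
    pi1 <- asymmetry_index(s)
    pi2 <- asymmetry_index(rev_rr(s))
    expect_equal(pi1 + pi2, 100, tolerance = 1e-12)
  }

  const <- rr_series(rep(800, 200))
  expect_true(is.na(asymmetry_index(const)))
  expect_error(asymmetry_index(rr_series(rep(c(800, 820), 10))),
               class = "hrvrisk_too_few_points")
})

test_that("Guzik index is consistent with the distance-based definition", {
  alt <- rr_series(c(rep(c(800, 850), 100), 800))
  expect_equal(asymmetry_index(alt, "guzik"), 50.0)
  ramp <- rr_series(seq(700, 900, length.out = 150))
  expect_equal(asymmetry_index(ramp, "guzik"), 100.0)
})

test_that("metrics are invariant to prepending invalid-flagged intervals", {
  x <- gen_rr("physiologic", 1400, 800, 30, seed = 31)
  pre <- rr_series(c(2500, 2600, 250, x$rr_ms),
                   valid = c(FALSE, FALSE, FALSE, x$valid))
  expect_identical(dfa_alpha1(pre), dfa_alpha1(x))
  expect_identical(sample_entropy(pre), sample_entropy(x))
  expect_identical(fuzzy_entropy(pre), fuzzy_entropy(x))
  expect_equal(mean_rr(pre), mean_rr(x))
  expect_equal(asymmetry_index(pre), asymmetry_index(x))
  a <- powerlaw_fit(pre); b <- powerlaw_fit(x)
  expect_equal(a$slope, b$slope, tolerance = 1e-8)
  expect_equal(a$r2, b$r2, tolerance = 1e-8)
})

test_that("compute_panel produces a finite panel on a physiologic fixture", {
  rr <- clean_rr(gen_rr("physiologic", 1900, 800, 30, seed = 8))  # ~25 min
  q <- assess_quality(rr)
  expect_equal(q$verdict, "OK")
  panel <- compute_panel(rr, respiratory_rate_bpm = 18, quality = q)
  expect_s3_class(panel, "hrv_panel")
  vals <- tidy(panel)$value
  expect_true(all(is.finite(vals)))
  expect_equal(panel$n_valid_rr, sum(rr$valid))

  panel2 <- compute_panel(rr, respiratory_rate_bpm = 18, quality = q)
  expect_identical(tidy(panel)$value, tidy(panel2)$value)
})

test_that("compute_panel refuses with a typed no-score signal, not an error", {
  short <- clean_rr(gen_rr("white", 700, 800, 20, seed = 9))  # ~9 min
  q <- assess_quality(short)
  expect_equal(q$verdict, "TOO_SHORT")
  res <- compute_panel(short, 18, q)
  expect_s3_class(res, "sa_no_score")
  expect_equal(res$reason, "TOO_SHORT")
  expect_match(res$detail, "15")
})
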