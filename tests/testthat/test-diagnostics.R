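test_that("MAI profile separates white from dependent series", {
  set.seed(10)
  x <- rnorm(10000)
  pr <- mai_profile(x, seed = 1)
  expect_true(all(pr$mai >= 0))
  expect_true(isTRUE(mai_whiteness(pr)))
  # hard lag-1 dependence stands far above the reference
  y <- rep(rnorm(5000), each = 2)  # c_t = c_{t-1} pairing
  pry <- mai_profile(y, seed = 2)
  expect_gt(pry$mai[1], pry$reference + 10 * pry$reference_sd)
  # AR(1): MAI decays with lag and is positive out to ~1/tau
  tau <- 0.01
  z <- as.numeric(stats::filter(rnorm(20000), 1 - tau,
                                method = "recursive"))
  prz <- mai_profile(z, seed = 3)
  expect_gt(prz$mai[1], prz$mai[which(prz$lags >= 300)[1]])
  expect_gt(prz$mai[which(prz$lags >= 90)[1]],
            prz$reference + 3 * prz$reference_sd)
  # closed-form Gaussian MI at lag 1: -0.5 log(1 - rho^2), rho = 1 - tau
  expect_equal(prz$mai[1], -0.5 * log(1 - (1 - tau)^2), tolerance = 0.25)
  # invariance under monotone/affine transforms
  pr2 <- mai_profile(3 * x - 100, seed = 1)
  expect_equal(pr2$mai, pr$mai)
  # constant series: zero MAI by convention
  expect_true(all(mai_profile(rep(1, 5000), seed = 4)$mai == 0))
})

test_that("MAI normalization anchors reference to 0 and lag-1 to 1", {
  set.seed(20)
  z <- as.numeric(stats::filter(rnorm(8000), 0.95, method = "recursive"))
  pr <- normalize_mai(mai_profile(z, seed = 5))
  expect_equal(pr$normalized[1], 1)
  expect_false(pr$degenerate)
  # flat profile normalized against a correlated anchor scatters near 0
  w <- mai_profile(rnorm(8000), seed = 6)
  nw <- normalize_mai(w, anchor = mai_profile(z, seed = 5))
  expect_lt(max(abs(nw$normalized)), 0.2)
  # degenerate anchor (constant series: zero MAI everywhere) flagged
  const <- mai_profile(rep(1, 4000), seed = 7)
  expect_warning(nd <- normalize_mai(const), "reference")
  expect_true(nd$degenerate)
})

test_that("MS2D measures bias roughness", {
  day <- rep(0L, 1999)
  # linear bias: second derivative zero
  expect_equal(ms2d(seq(0, 10, length.out = 1999), day), 0,
               tolerance = 1e-18)
  # quadratic bias on a grid that resamples exactly: constant second
  # difference 2 * step^2 with step (1999-1)/999 = 2, so MS2D = 64
  expect_equal(ms2d((1:1999)^2, day), 64, tolerance = 1e-6)
  # white-noise bias is much rougher than a smooth one
  set.seed(30)
  rough <- ms2d(rnorm(1000), rep(0L, 1000))
  smooth <- ms2d(sin(seq(0, 3, length.out = 1000)), rep(0L, 1000))
  expect_gt(rough, 100 * smooth)
  # short days are skipped with a warning
  expect_warning(ms2d(c(1, 2, rnorm(500)), c(0L, 0L, rep(1L, 500))),
                 "skipped")
})

test_that("smoothed RMSE behaves under offset and noise", {
  x <- rnorm(500) + 1000
  expect_equal(smoothed_rmse(x, x), 0)
  expect_equal(smoothed_rmse(x + 3, x), 3, tolerance = 1e-10)
  # smoothing shrinks discrepancies that are zero-mean noise
  set.seed(40)
  y <- x + rnorm(500, 0, 5)
  expect_lt(smoothed_rmse(y, x), sqrt(mean((y - x)^2)))
  expect_error(smoothed_rmse(x[1:10], x), "length")
})

test_that("normalized final pitch maps the threshold excursion to [0,1]", {
  thr <- c(rep(1000, 50), rep(1020, 50))
  pitch <- c(rnorm(50, 1005, 1), rnorm(50, 1020, 1e-9))
  tr <- pitch_trajectory(day = rep(0:1, each = 50),
                         h = rep(seq(0.3, 0.8, length.out = 50), 2),
                         pitch = pitch, hit = pitch < thr, threshold = thr,
                         contingency = "low")
  expect_equal(normalized_final_pitch(tr), 1, tolerance = 1e-6)
  tr2 <- tr
  tr2$pitch[51:100] <- 1000
  tr2$hit <- tr2$pitch < tr2$threshold
  expect_equal(normalized_final_pitch(tr2), 0, tolerance = 1e-6)
  expect_error(normalized_final_pitch(tr, 1000, 1000), "undefined")
})

test_that("d-prime is a symmetric standardized mean difference", {
  set.seed(50)
  a <- rnorm(200)
  expect_equal(dprime(a, a), 0)
  b <- rnorm(200, 1, 1)
  expect_equal(dprime(a, b), -dprime(b, a))
  expect_equal(dprime(rnorm(4000, 1, 1), rnorm(4000, 0, 1)), 1,
               tolerance = 0.1)
  expect_error(dprime(rep(1, 5), rep(1, 5)), "zero pooled")
})

test_that("autocorrelation matches the AR(1) closed form", {
  set.seed(60)
  ac <- autocorrelation(rnorm(5000), 10)
  expect_equal(ac[1], 1)
  expect_lt(max(abs(ac[-1])), 0.05)
  z <- as.numeric(stats::filter(rnorm(50000), 0.9, method = "recursive"))
  acz <- autocorrelation(z, 20)
  expect_equal(acz[2], 0.9, tolerance = 0.03)
  expect_equal(acz[11], 0.9^10, tolerance = 0.05)
})
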