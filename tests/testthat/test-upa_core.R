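test_that("empirical_cdf is the right-continuous counting CDF", {
  F <- empirical_cdf(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(F(0.4), 0.5) # 2 of 4 values <= 0.4
  expect_equal(F(0.1), 0)
  expect_equal(F(0.8), 1)
  expect_equal(F(0.41), 0.5) # right-continuous step

  set.seed(11)
  x <- runif(200)
  q <- runif(50)
  G <- empirical_cdf(x)
  brute <- vapply(q, function(g) sum(x <= g) / length(x), numeric(1))
  expect_equal(G(q), brute)

  expect_error(empirical_cdf(numeric(0)), "at least one")
})

test_that("fitting on coinciding distributions yields the identity at knots", {
  ref <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  tr <- fit_alignment(ref, ref)
  expect_equal(tr$source_knots, ref)
  expect_equal(tr$target_knots, ref)
  expect_equal(apply_alignment(tr, ref), ref)
  expect_equal(tr$fit_size, 5L)
  expect_equal(tr$reference_size, 5L)
})

test_that("a pure location shift of the scores is inverted at every knot", {
  ref <- seq(0.1, 0.8, by = 0.1)
  al <- ref + 0.1
  tr <- fit_alignment(ref, al)
  expect_equal(apply_alignment(tr, al), al - 0.1, tolerance = 1e-12)
})

test_that("fitted knots match the brute-force quantile-matching oracle", {
  set.seed(7)
  ref <- runif(50)
  al <- runif(40)
  tr <- fit_alignment(ref, al)
  oracle <- oracle_quantile_match(ref, al)
  expect_equal(tr$source_knots, oracle$source)
  expect_lt(max(abs(tr$target_knots - oracle$target)), 1e-10)
})

test_that("fit refuses degenerate alignment sets and out-of-range scores", {
  expect_error(fit_alignment(runif(10), 0.4), "at least 2")
  expect_error(fit_alignment(runif(10), rep(0.4, 5)), "distinct")
  expect_error(fit_alignment(c(0.2, 1.4), runif(5)), "outside")
  expect_error(fit_alignment(runif(10), c(0.2, -0.1)), "outside")
  expect_error(apply_alignment(fit_alignment(runif(9), runif(9)), 1.2),
               "outside")
})

test_that("application interpolates linearly and extrapolates monotonically", {
  tr <- structure(list(source_knots = c(0.2, 0.4), target_knots = c(0.1, 0.3),
                       fit_size = 2L, reference_size = 2L),
                  class = "alignment_transform")
  expect_equal(apply_alignment(tr, 0.3), 0.2)   # midpoint of the segment
  expect_equal(apply_alignment(tr, c(0.2, 0.4)), c(0.1, 0.3)) # at the knots
  expect_equal(apply_alignment(tr, 0.5), 0.4)   # linear continuation
  expect_equal(apply_alignment(tr, 1), 0.9)
  expect_equal(apply_alignment(tr, 0.05), 0)    # clipped at the domain floor

  set.seed(23)
  for (i in 1:10) {
    tr2 <- fit_alignment(runif(60), runif(40))
    x <- sort(runif(100))
    y <- apply_alignment(tr2, x)
    expect_true(all(diff(y) >= 0)) # monotone non-decreasing
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("alignment preserves ROC-AUC exactly without ties, boundedly with", {
  set.seed(31)
  ref <- runif(500)
  scores <- runif(400)
  labels <- rbinom(400, 1, plogis(6 * (scores - 0.5)))
  tr <- fit_alignment(ref, scores)
  aligned <- apply_alignment(tr, scores)
  expect_lt(abs(roc_auc(scores, labels) - roc_auc(aligned, labels)), 1e-12)

  # with ties: the change is bounded by half the tied pos-neg pair mass
  tied <- round(scores, 2)
  tr2 <- fit_alignment(ref, tied)
  aligned2 <- apply_alignment(tr2, tied)
  bound <- 0.5 * (tied_pair_fraction(tied, labels) +
                    tied_pair_fraction(aligned2, labels))
  expect_lte(abs(roc_auc(tied, labels) - roc_auc(aligned2, labels)), bound)
})

test_that("aligned scores match the reference distribution (KS shrinks)", {
  set.seed(41)
  ref <- plogis(rnorm(5000, 0.5))
  shifted <- plogis(rnorm(5000, -0.8)) # location-shifted domain
  before <- detect_shift(ref, shifted)$statistic
  tr <- fit_alignment(ref, shifted)
  after <- detect_shift(ref, apply_alignment(tr, shifted))$statistic
  expect_lt(after, before)
  expect_lt(after, 0.05)
})

test_that("self-alignment converges to the identity map", {
  set.seed(53)
  ref <- runif(5000)
  al <- runif(5000)
  tr <- fit_alignment(ref, al)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_lt(mean(abs(apply_alignment(tr, grid) - grid)), 0.02)
})

test_that("alignment inverts a strictly monotone warp on the interior", {
  set.seed(67)
  base <- plogis(rnorm(5000, 0.3))
  warp <- warp_affine_latent(shift = -1)
  shifted <- apply_warp(warp, plogis(rnorm(5000, 0.3)))
  tr <- fit_alignment(base, shifted)
  qs <- quantile(shifted, c(0.05, 0.95))
  grid <- seq(qs[1], qs[2], length.out = 200)
  g_inv <- plogis(qlogis(grid) + 1)
  expect_lt(max(abs(apply_alignment(tr, grid) - g_inv)), 0.03)
})

test_that("detect_shift computes the two-sample KS distance", {
  x <- runif(40, 0, 1)
  expect_equal(detect_shift(x, x)$statistic, 0)
  expect_false(detect_shift(x, x)$flagged)

  lo <- runif(30, 0.0, 0.1)
  hi <- runif(30, 0.9, 1.0)
  d <- detect_shift(lo, hi)
  expect_equal(d$statistic, 1)
  expect_true(d$flagged)

  set.seed(71)
  a <- plogis(rnorm(120))
  b <- plogis(rnorm(80, 0.4))
  expect_equal(detect_shift(a, b)$statistic, oracle_ks(a, b))
  # agreement with the classical two-sample statistic
  expect_equal(detect_shift(a, b)$statistic,
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
})

test_that("a transform survives a JSON round trip bit-identically", {
  set.seed(83)
  tr <- fit_alignment(runif(200), runif(150))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_identical(back$source_knots, tr$source_knots)
  expect_identical(back$target_knots, tr$target_knots)
  expect_identical(back$fit_size, tr$fit_size)
  x <- runif(100)
  expect_identical(apply_alignment(back, x), apply_alignment(tr, x))
})
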