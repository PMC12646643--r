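test_that("sampled histograms are reproducible and match the model distribution", {
  th <- telegraph_params(0.05, 0.1, 10)
  h1 <- sample_histogram(th, N = 1, seed = 2)
  expect_equal(sum(h1$n), 1)
  h <- sample_histogram(th, N = 500, seed = 2)
  expect_identical(h, sample_histogram(th, N = 500, seed = 2))
  expect_equal(sum(h$n), 500)

  # Poisson limit: sample mean within 3 SE of ksyn
  hp <- sample_histogram(telegraph_params(1e3, 1e-3, 5), N = 1e5, seed = 9)
  m <- sum(hp$x * hp$n) / sum(hp$n)
  expect_lt(abs(m - 5), 3 * sqrt(5 / 1e5))

  # chi-square GOF against the model marginal across seeds: rejections at
  # the nominal rate
  p <- as.numeric(steady_marginal(th))
  rej <- 0L
  for (s in 1:50) {
    hs <- sample_histogram(th, N = 1e4, seed = 100 + s)
    xs <- rep(hs$x, hs$n)
    if (chisq_gof_p(xs, p) < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 7L)  # Binomial(50, 0.05): P(X > 7) < 0.004
})

test_that("empirical distributions converge to the marginal as N grows", {
  th <- telegraph_params(0.23, 0.1, 3.5)
  p <- as.numeric(steady_marginal(th))
  tv <- vapply(c(100, 1e4, 1e6), function(N) {
    h <- sample_histogram(th, N = N, seed = 77)
    emp <- numeric(length(p))
    emp[h$x + 1L] <- h$n / sum(h$n)
    tv_dist(emp, p)
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
})

test_that("bootstrap replicate fits are seeded deterministically", {
  lib <- cached_library(6, beta = 1)
  bs <- bootstrap_mles(telegraph_params(0.23, 0.1, 3.5), lib, N = 200,
                       n_reps = 3, seed = 5)
  expect_equal(nrow(bs$mles), 3L)
  expect_equal(length(bs$histograms), 3L)
  bs2 <- bootstrap_mles(telegraph_params(0.23, 0.1, 3.5), lib, N = 200,
                        n_reps = 3, seed = 5)
  expect_identical(bs$mles, bs2$mles)
  td <- tidy(bs)
  expect_equal(nrow(td), 9L)
  expect_equal(unique(td$true[td$term == "ksyn"]), 3.5)
})

test_that("summary statistics capture dispersion and shape", {
  # Poisson limit: Fano factor 1, a single interior mode
  sp <- summary_statistics(steady_marginal(telegraph_params(1e3, 1e-3, 5)))
  expect_equal(sp$fano, 1, tolerance = 1e-2)
  expect_equal(sp$n_modes, 1L)
  # point mass: zero variance and Fano
  sd_ <- summary_statistics(count_histogram(rep(3L, 10)))
  expect_equal(sd_$variance, 0)
  expect_equal(sd_$fano, 0)
  # bursty regime: super-Poissonian
  sb <- summary_statistics(steady_marginal(telegraph_params(0.05, 0.1, 10)))
  expect_gt(sb$fano, 1)
  # bimodal regime: an interior mode next to the zero spike
  sm <- summary_statistics(steady_marginal(telegraph_params(0.05, 0.05, 10)))
  expect_gte(sm$n_modes, 1L)
  expect_gt(sm$zero_fraction, 0.3)
  # zero-mean input: Fano undefined
  s0 <- summary_statistics(count_histogram(rep(0L, 4)))
  expect_true(is.na(s0$fano))
})
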