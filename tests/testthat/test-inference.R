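test_that("log-likelihood is the count-weighted log model probability", {
  th <- telegraph_params(0.05, 0.1, 10)
  p <- steady_marginal(th)
  h0 <- count_histogram(rep(0L, 5))
  expect_equal(log_likelihood(h0, th), 5 * log(p[1]), tolerance = 1e-12)
  h <- sample_histogram(th, N = 100, seed = 3)
  h2 <- dplyr::mutate(h, n = 2 * n)
  expect_equal(log_likelihood(h2, th), 2 * log_likelihood(h, th),
               tolerance = 1e-12)
  # counts beyond the truncated support stay finite through the floor
  far <- count_histogram(c(0L, 5000L))
  expect_true(is.finite(log_likelihood(far, th)))
  expect_error(log_likelihood(tibble::tibble(x = integer(), n = numeric()),
                              th), "empty")
})

test_that("APM follows its closed form and the overall value is the worst parameter", {
  expect_equal(apm(2, 2, T = 100), 0)
  expect_equal(apm(0.05, 5, T = 100), 1)
  expect_equal(apm(1, 100, T = 100), 1)
  expect_equal(apm(1, 9, T = 3), 2)
  expect_error(apm(0, 1, T = 100), "positive")
  # strictly decreasing in T for a fixed CI
  expect_gt(apm(1, 50, T = 3), apm(1, 50, T = 100))

  out <- classify_identifiability(c(0.2, 0.5, 0.9))
  expect_equal(out$overall_apm, 0.9)
  expect_true(out$identifiable)
  out2 <- classify_identifiability(c(0.2, 0.5, 1.5))
  expect_equal(out2$overall_apm, 1.5)
  expect_false(out2$identifiable)
})

test_that("CI extraction from a quadratic profile matches the closed form", {
  v0 <- 0.5
  for (c_curv in c(2, 10, 50)) {
    vals <- seq(-2, 3, length.out = 2001)
    pl <- 7 + c_curv * (vals - v0)^2
    cr <- burstid:::ci_from_profile(vals, pl, 7, 1.92)
    hw <- sqrt(1.92 / c_curv)
    expect_equal(cr$lb_log10, v0 - hw, tolerance = 1e-3)
    expect_equal(cr$ub_log10, v0 + hw, tolerance = 1e-3)
    expect_false(cr$lb_boundary); expect_false(cr$ub_boundary)
  }
  # curve never crossing on the right: bound at the edge, flagged
  vals <- seq(-2, 3, length.out = 51)
  pl <- 7 + pmax(0, -2 - vals) * 100  # flat except far left
  cr <- burstid:::ci_from_profile(vals, pl, 7, 1.92)
  expect_true(cr$ub_boundary)
  expect_equal(cr$ub_log10, 3)
})

test_that("MLE recovers a grid-point truth from its exact distribution", {
  lib <- cached_library(6, beta = 1)
  i <- 130L  # interior-ish grid point
  theta <- telegraph_params(lib$points$kon[i], lib$points$koff[i],
                            lib$points$ksyn[i])
  tgt <- apriori_target(theta, N = 1e4)
  fit <- fit_mle(burstid:::target_histogram(tgt), lib)
  expect_lt(max(abs(as.numeric(fit$theta) - as.numeric(theta)) /
                  as.numeric(theta)), 1e-3)
  expect_lte(fit$minus_ll, fit$coarse_minus_ll + 1e-9)
  expect_false(fit$fallback)
})

test_that("degenerate all-zero data pins the MLE at a range boundary", {
  lib <- cached_library(6, beta = 1)
  fit <- fit_mle(count_histogram(rep(0L, 50)), lib)
  expect_true(any(fit$boundary))
})

test_that("profile likelihoods satisfy the envelope and bracket the MLE", {
  lib <- cached_library(6, beta = 1)
  tgt <- apriori_target(telegraph_params(0.23, 0.1, 3.5), N = 200)
  pr <- profile_likelihood(burstid:::target_histogram(tgt), lib,
                           control = fast_control())
  expect_true(all(pr$profiles$minus_ll >= pr$minus_ll_min - 1e-6))
  expect_equal(pr$overall_apm, max(pr$ci$apm))
  for (par in c("kon", "koff", "ksyn")) {
    row <- pr$ci[pr$ci$param == par, ]
    est <- pr$mle$theta[[par]]
    if (!row$lb_boundary) expect_lte(row$lb, est * (1 + 1e-6))
    if (!row$ub_boundary) expect_gte(row$ub, est * (1 - 1e-6))
  }
  # the sampling-free profile recovers the truth as its optimum
  expect_equal(pr$minus_ll_min, cross_entropy(tgt, tgt$theta_tar),
               tolerance = 1e-4)
})

test_that("tidiers return one row per term and a one-row glance", {
  lib <- cached_library(6, beta = 1)
  h <- sample_histogram(telegraph_params(0.23, 0.1, 3.5), N = 300, seed = 5)
  fit <- fit_mle(h, lib)
  td <- tidy(fit)
  expect_equal(td$term, c("kon", "koff", "ksyn"))
  expect_equal(td$estimate, as.numeric(fit$theta))
  expect_equal(nrow(glance(fit)), 1L)
  pr <- profile_likelihood(h, lib, control = fast_control(), fit = fit)
  tp <- tidy(pr)
  expect_equal(nrow(tp), 3L)
  expect_true(all(c("estimate", "lb", "ub", "apm") %in% names(tp)))
  gl <- glance(pr)
  expect_equal(gl$overall_apm, pr$overall_apm)
  expect_s3_class(autoplot(pr), "ggplot")
})
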