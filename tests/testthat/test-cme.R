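test_that("rate matrix matches brute-force reaction enumeration and is a generator", {
  set.seed(4711)
  cases <- list(c(0.05, 0.1, 10), c(1, 1, 2), c(30, 0.3, 150))
  for (th in cases) {
    M <- 60L
    A <- build_rate_matrix(telegraph_params(th[1], th[2], th[3]), M)
    expect_equal(dim(A), c(2L * (M + 1L), 2L * (M + 1L)))
    expect_lt(max(abs(Matrix::colSums(A))), 1e-12)
    B <- enum_rate_matrix(th[1], th[2], th[3], M)
    expect_equal(as.matrix(A), B, ignore_attr = TRUE, tolerance = 1e-14)
    offdiag <- as.matrix(A); diag(offdiag) <- 0
    expect_true(all(offdiag >= 0))
  }
  expect_error(build_rate_matrix(telegraph_params(1, 1, 1), 0), "M")
  expect_error(telegraph_params(-1, 1, 1), "positive")
})

test_that("steady state solves A p = 0 with controlled truncation error", {
  cases <- list(c(0.05, 0.1, 10), c(0.23, 0.1, 3.5), c(2, 5, 50),
                c(0.01, 0.01, 0.6), c(30, 30, 150))
  for (th in cases) {
    ss <- steady_state(telegraph_params(th[1], th[2], th[3]))
    expect_lt(ss$residual, 1e-10)
    expect_equal(sum(ss$probabilities), 1, tolerance = 1e-12)
    expect_true(all(ss$probabilities >= 0))
    expect_lte(ss$tail_mass_error, 1e-4)
    # doubling the truncation never increases the estimated tail mass
    M <- ss$truncation_bound
    tail_m <- function(MM) {
      marg <- colSums(burstid:::solve_cme_fixed(
        telegraph_params(th[1], th[2], th[3]), MM)$joint)
      sum(marg[c(MM, MM + 1L)])
    }
    expect_lte(tail_m(2L * M), tail_m(M) + 1e-15)
  }
})

test_that("marginal matches the analytic Beta-Poisson stationary law", {
  set.seed(99)
  sets <- oracle_param_sets()
  for (i in seq_len(nrow(sets))) {
    th <- sets[i, ]
    p <- steady_marginal(telegraph_params(th$kon, th$koff, th$ksyn))
    q <- beta_poisson_pmf(seq_along(p) - 1, th$kon, th$koff, th$ksyn)
    expect_lt(tv_dist(p, q), 1e-4)
  }
})

test_that("closed-form mean and the always-on Poisson limit are recovered", {
  for (th in list(c(0.05, 0.1, 10), c(0.5, 2, 20), c(5, 0.7, 3))) {
    p <- steady_marginal(telegraph_params(th[1], th[2], th[3]))
    expect_equal(sum((seq_along(p) - 1) * as.numeric(p)),
                 th[3] * th[1] / (th[1] + th[2]), tolerance = 1e-6)
  }
  p <- steady_marginal(telegraph_params(1e3, 1e-3, 5))
  expect_lt(tv_dist(p, dpois(seq_along(p) - 1, 5)), 1e-3)
})

test_that("marginal agrees with Gillespie simulation (chi-square GOF)", {
  cases <- list(list(th = c(0.5, 1, 10), t_end = 25, seed = 42),
                list(th = c(1, 2, 20), t_end = 25, seed = 43),
                list(th = c(0.23, 0.1, 3.5), t_end = 40, seed = 44))
  for (cs in cases) {
    theta <- telegraph_params(cs$th[1], cs$th[2], cs$th[3])
    xs <- ssa_sample(theta, 1e5, t_end = cs$t_end, seed = cs$seed)
    p <- as.numeric(steady_marginal(theta))
    expect_gt(chisq_gof_p(xs, p), 0.01)
  }
})

test_that("conditional distributions recombine to the marginal with stationary occupancies", {
  th <- telegraph_params(0.23, 0.1, 3.5)
  joint <- steady_state(th)
  cond <- conditional_distributions(joint)
  expect_equal(sum(cond$inactive), 1, tolerance = 1e-12)
  expect_equal(sum(cond$active), 1, tolerance = 1e-12)
  expect_equal(unname(cond$occupancy["active"]), 0.23 / 0.33,
               tolerance = 1e-6)
  recomb <- cond$occupancy[["inactive"]] * as.numeric(cond$inactive) +
    cond$occupancy[["active"]] * as.numeric(cond$active)
  expect_equal(recomb, as.numeric(marginalize(joint)), tolerance = 1e-12)
  # mode separation between the two promoter states drives bimodality
  expect_equal(which.max(cond$inactive) - 1L, 0L)
  expect_equal(which.max(cond$active) - 1L, 3L)

  # always-on limit: conditional on the active state is Poisson(ksyn)
  cond_on <- conditional_distributions(steady_state(telegraph_params(1e3, 1e-3, 5)))
  expect_lt(tv_dist(cond_on$active, dpois(0:(length(cond_on$active) - 1), 5)),
            1e-3)
  # symmetric switch: both occupancies 1/2
  cond_sym <- conditional_distributions(steady_state(telegraph_params(0.4, 0.4, 8)))
  expect_equal(unname(cond_sym$occupancy), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("burst summaries follow the closed forms", {
  out <- burst_summaries(telegraph_params(0.05, 0.1, 10))
  expect_equal(out$burst_size, 100)
  expect_equal(out$burst_frequency, 0.005 / 0.15)
  expect_equal(out$mean_expression, 10 * 0.05 / 0.15)
  expect_equal(burst_summaries(telegraph_params(0.7, 0.7, 3))$burst_frequency,
               0.35)
  expect_equal(burst_summaries(telegraph_params(1, 2.5, 2.5))$burst_size, 1)
})
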