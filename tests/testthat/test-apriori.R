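test_that("cross-entropy is minimized at the truth (Gibbs) and is linear in N", {
  tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
  p <- as.numeric(tgt$p_tar)
  H0 <- cross_entropy(tgt, tgt$theta_tar)
  expect_equal(H0, -200 * sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-6)
  set.seed(23)
  for (i in 1:10) {
    pert <- telegraph_params(0.05 * 10^runif(1, -0.5, 0.5),
                             0.1 * 10^runif(1, -0.5, 0.5),
                             10 * 10^runif(1, -0.3, 0.3))
    expect_gte(cross_entropy(tgt, pert), H0 - 1e-9)
  }
  tgt2 <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 400)
  cand <- telegraph_params(0.1, 0.2, 8)
  expect_equal(cross_entropy(tgt2, cand), 2 * cross_entropy(tgt, cand),
               tolerance = 1e-9)
})

test_that("profile curves rescale exactly across cell numbers and CIs nest", {
  lib <- cached_library(6, beta = 1)
  tgt <- apriori_target(telegraph_params(0.23, 0.1, 3.5), N = 100)
  pr100 <- ground_truth_profile(tgt, lib, control = fast_control())
  pr400 <- burstid:::rescale_profile(pr100, 400)
  expect_equal(pr400$minus_ll_min, 4 * pr100$minus_ll_min, tolerance = 1e-9)
  # larger N: every CI at least as narrow (up to interpolation slack of one
  # profile-grid step)
  step <- 6 / 14
  for (par in c("kon", "koff", "ksyn")) {
    r1 <- pr100$ci[pr100$ci$param == par, ]
    r4 <- pr400$ci[pr400$ci$param == par, ]
    expect_lte(log10(r4$ub / r4$lb), log10(r1$ub / r1$lb) + step)
  }
  expect_lte(pr400$overall_apm, pr100$overall_apm + 1e-9)
})

test_that("a direct rerun of the ground-truth profile is deterministic", {
  lib <- cached_library(6, beta = 1)
  tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
  a <- ground_truth_profile(tgt, lib, control = fast_control())
  b <- ground_truth_profile(tgt, lib, control = fast_control())
  expect_identical(a$ci, b$ci)
  expect_identical(a$profiles$minus_ll, b$profiles$minus_ll)
})

test_that("capture-rate mismatch between target and library is an error", {
  lib <- cached_library(6, beta = 1)
  tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200, beta = 0.3)
  expect_error(ground_truth_profile(tgt, lib), "capture rate")
})

test_that("cell ladder reports the smallest identifiable N without refitting", {
  lib <- cached_library(6, beta = 1)
  res <- cells_for_identifiability(telegraph_params(0.23, 0.1, 3.5), lib,
                                   N_ladder = c(1e3, 1e4),
                                   control = fast_control())
  expect_equal(res$N_min, 1e3)
  expect_true(all(diff(res$ladder$apm_max) <= 1e-9))  # monotone in N
})

test_that("reduced landscape scans show the expected qualitative structure", {
  lib1 <- cached_library(12, beta = 1)
  lib03 <- cached_library(12, beta = 0.3)
  sub <- grid_spec(n = 5)
  L1 <- scan_landscape(sub, lib1, N = 1e4)
  L03 <- scan_landscape(sub, lib03, N = 1e4)
  expect_true(all(L1$ok), all(L03$ok))
  # dropout degrades identifiability (fraction-level pattern; per-point
  # coarse-screen APMs carry grid-quantization jitter)
  expect_lte(mean(L03$identifiable), mean(L1$identifiable))
  # identifiable points sit at slow promoter deactivation
  expect_lt(median(L1$koff[L1$identifiable]),
            median(L1$koff[!L1$identifiable]))
  # the identifiable region grows from the lowest synthesis rates
  frac_by_ksyn <- tapply(L1$identifiable, L1$ksyn, mean)
  expect_lt(frac_by_ksyn[[1]], max(frac_by_ksyn[-1]))
  # a single cell identifies nothing
  L1cell <- scan_landscape(grid_spec(n = 3), lib1, N = 1)
  expect_equal(mean(L1cell$identifiable), 0)
  # determinism
  expect_identical(scan_landscape(sub, lib1, N = 1e4), L1)
})
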