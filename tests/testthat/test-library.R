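test_that("library build enumerates the grid with normalized distributions", {
  lib <- build_model_library(grid_spec(n = 2), beta = 1)
  expect_equal(nrow(lib$points), 8L)
  expect_true(all(lib$points$ok))
  for (d in lib$distributions) expect_equal(sum(d), 1, tolerance = 1e-12)
  # kon-major ordering: ksyn varies fastest
  expect_equal(lib$points$ksyn[1:2], 10^c(-0.3, 2.3))
  expect_equal(lib$points$kon[1:4], rep(1e-3, 4))
})

test_that("downsampled library entries match thinning the beta = 1 entries", {
  lib1 <- cached_library(6, beta = 1)
  lib03 <- cached_library(6, beta = 0.3)
  set.seed(31)
  for (i in sample(nrow(lib1$points), 20)) {
    thinned <- downsample_distribution(lib1$distributions[[i]], 0.3)
    expect_lt(tv_dist(thinned, lib03$distributions[[i]]), 1e-6)
  }
})

test_that("serialization round-trips the library exactly", {
  lib <- build_model_library(grid_spec(n = 2), beta = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_library(lib, path)
  back <- read_model_library(path)
  expect_identical(back$distributions, lib$distributions)
  expect_equal(back$beta, lib$beta)
  expect_equal(back$grid, lib$grid)
  expect_equal(back$points, lib$points)
})

test_that("coarse surface argmin recovers each grid point used as its own target", {
  lib <- cached_library(6, beta = 1)
  set.seed(17)
  for (i in sample(nrow(lib$points), 10)) {
    theta <- telegraph_params(lib$points$kon[i], lib$points$koff[i],
                              lib$points$ksyn[i])
    tgt <- apriori_target(theta, N = 500)
    surf <- coarse_surface(burstid:::target_histogram(tgt), lib)
    expect_equal(which.min(surf$minus_ll), i)
  }
})

test_that("coarse surface is linear in the cell number", {
  lib <- cached_library(6, beta = 1)
  tgt1 <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 1)
  tgt200 <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
  s1 <- coarse_surface(burstid:::target_histogram(tgt1), lib)
  s200 <- coarse_surface(burstid:::target_histogram(tgt200), lib)
  expect_equal(s200$minus_ll, 200 * s1$minus_ll, tolerance = 1e-9)
})

test_that("single-cell zero-count target minimizes -LL where P0 is largest", {
  lib <- cached_library(6, beta = 1)
  surf <- coarse_surface(count_histogram(0L), lib)
  p0 <- vapply(lib$distributions, function(p) p[1], numeric(1))
  expect_equal(which.min(surf$minus_ll), which.max(p0))
  expect_equal(min(surf$minus_ll), -log(max(p0)), tolerance = 1e-12)
})

test_that("search bounds enclose the low -LL region and expand by one grid step", {
  lib <- cached_library(6, beta = 1)
  tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
  surf <- coarse_surface(burstid:::target_histogram(tgt), lib)
  b <- search_bounds_from_surface(surf, lib$grid)
  sel <- surf[surf$minus_ll <= min(surf$minus_ll) + 1.92 + 2, ]
  for (par in c("kon", "koff", "ksyn")) {
    expect_lte(b$lower[[par]], min(log10(sel[[par]])))
    expect_gte(b$upper[[par]], max(log10(sel[[par]])))
  }
  expect_equal(unname(b$init["kon"]),
               log10(surf$kon[which.min(surf$minus_ll)]))

  # flat surface: bounds degenerate to the full grid range
  flat <- dplyr::mutate(surf, minus_ll = 1)
  bf <- search_bounds_from_surface(flat, lib$grid)
  expect_equal(unname(bf$lower), c(-3, -3, -0.3), tolerance = 1e-12)
  expect_equal(unname(bf$upper), c(3, 3, 2.3), tolerance = 1e-12)
})

test_that("empty or invalid histograms are rejected", {
  lib <- cached_library(6, beta = 1)
  expect_error(coarse_surface(tibble::tibble(x = integer(), n = numeric()),
                              lib), "empty")
  expect_error(count_histogram(c(-1, 2)), "nonnegative")
  expect_error(as_count_histogram(tibble::tibble(x = 1, n = 2),
                                  allow_fractional = FALSE), NA)
})
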