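test_that("dose_grid and gamma_criteria validate their invariants", {
  expect_error(dose_grid(1:10, 3), "matrix or 3D")
  expect_error(dose_grid(matrix(-1, 4, 4), 3), "non-negative")
  expect_error(dose_grid(matrix(1, 4, 4), c(-3, 3)), "positive")
  expect_error(gamma_criteria(0, 3), "> 0")
  expect_error(gamma_criteria(3, 3, search_cap_mm = 1), ">=")
  g <- dose_grid(matrix(10, 4, 4), 3)
  h <- dose_grid(matrix(10, 5, 5), 3)
  expect_error(compute_gamma(g, h, gamma_criteria(3, 3, norm_dose = 10)),
               "physical frame")
  expect_error(compute_gamma(g, g, gamma_criteria(3, 3, norm_dose = 0)),
               "> 0")
})

test_that("identical distributions give gamma 0 and full pass", {
  g <- make_phantom_grid(c(16L, 16L), 3, dpr = 60, target_radius_mm = 12)
  res <- compute_gamma(g, g, gamma_criteria(3, 3, norm_dose = 60))
  expect_equal(max(res$gamma), 0)
  expect_equal(res$pass_rate, 1.0)
  expect_equal(res$evaluated_count, 256L)
})

test_that("a uniform 3% offset sits exactly on the gamma = 1 boundary", {
  ref <- dose_grid(matrix(60, 12, 12), 3)
  ev <- dose_grid(matrix(60 * 1.03, 12, 12), 3)
  res <- compute_gamma(ref, ev, gamma_criteria(3, 3, norm_dose = 60))
  expect_equal(max(abs(res$gamma - 1)), 0, tolerance = 1e-9)
  # gamma == 1 counts as passing (inclusive criterion)
  expect_equal(res$pass_rate, 1.0)
  expect_equal(pass_rate(res, 0.999), 0.0)
})

test_that("a single raised voxel matches the brute-force oracle", {
  ref <- dose_grid(matrix(50, 9, 9), 3)
  evv <- matrix(50, 9, 9)
  evv[5, 5] <- 50 * 1.03          # raised by exactly the dd criterion
  ev <- dose_grid(evv, 3)
  # a lone impulse legitimately trips the advisory noise heuristic
  res <- suppressWarnings(
    compute_gamma(ref, ev, gamma_criteria(3, 3, norm_dose = 50)))
  ora <- oracle_gamma_2d(ref$values, evv, 3, 3, 3, 50)
  expect_lt(max(abs(res$gamma - ora)), 0.02)
  # with interpolated search the raised point dips below 1 but stays
  # well above 0; everywhere else the local match is perfect
  expect_gt(res$gamma[5, 5], 0.5)
  expect_lt(res$gamma[5, 5], 1)
  expect_equal(res$gamma[1, 1], 0)
  expect_equal(sum(res$gamma > 1e-9), 1L)
})

test_that("gamma agrees with the exhaustive fine-search oracle on random fields", {
  for (seed in 1:4) {
    ref_v <- random_dose_field(16, base = 50, seed = seed)
    ev_v <- random_dose_field(16, base = 50, seed = seed + 100) * 0.2 +
      ref_v * 0.82
    ref <- dose_grid(ref_v, 3)
    ev <- dose_grid(ev_v, 3)
    res <- compute_gamma(ref, ev, gamma_criteria(3, 3, norm_dose = 50))
    ora <- oracle_gamma_2d(ref_v, ev_v, 3, 3, 3, 50)
    expect_lt(max(abs(res$gamma - ora)), 0.02)
  }
})

test_that("tightening criteria never decreases gamma", {
  ref_v <- random_dose_field(12, base = 40, seed = 7)
  ev_v <- random_dose_field(12, base = 40, seed = 17)
  ref <- dose_grid(ref_v, 3)
  ev <- dose_grid(ev_v, 3)
  loose <- compute_gamma(ref, ev, gamma_criteria(3, 3, norm_dose = 40))
  tight_dd <- compute_gamma(ref, ev, gamma_criteria(2, 3, norm_dose = 40))
  tight_dta <- compute_gamma(ref, ev,
                             gamma_criteria(3, 2, norm_dose = 40,
                                            search_cap_mm = 9))
  expect_true(all(tight_dd$gamma >= loose$gamma - 1e-9))
  expect_true(all(tight_dta$gamma >= loose$gamma - 1e-9))
})

test_that("global gamma is invariant under joint rescaling of doses and norm", {
  ref_v <- random_dose_field(12, base = 40, seed = 3)
  ev_v <- ref_v * 1.05
  r1 <- compute_gamma(dose_grid(ref_v, 3), dose_grid(ev_v, 3),
                      gamma_criteria(3, 3, norm_dose = 40))
  k <- 2.5
  r2 <- compute_gamma(dose_grid(ref_v * k, 3), dose_grid(ev_v * k, 3),
                      gamma_criteria(3, 3, norm_dose = 40 * k))
  expect_equal(r1$gamma, r2$gamma, tolerance = 1e-9)
})

test_that("local normalization scales the dose criterion with local dose", {
  ref_v <- matrix(rep(c(20, 60), each = 32), 8, 8)
  ev_v <- ref_v * 1.02
  res <- compute_gamma(dose_grid(ref_v, 10), dose_grid(ev_v, 10),
                       gamma_criteria(2, 3, normalization = "local",
                                      search_cap_mm = 9))
  # a uniform 2% relative offset is exactly on the boundary everywhere
  # (flat regions; the 20/60 interface allows DTA rescue nearby)
  interior <- res$gamma[, c(1, 2, 7, 8)]
  expect_equal(max(abs(interior - 1)), 0, tolerance = 1e-9)
})

test_that("low-dose cutoff excludes points from evaluation", {
  ref_v <- matrix(c(rep(2, 32), rep(60, 32)), 8, 8)
  ev_v <- ref_v
  res <- compute_gamma(dose_grid(ref_v, 3), dose_grid(ev_v, 3),
                       gamma_criteria(3, 3, norm_dose = 60,
                                      low_dose_cutoff_percent = 10))
  expect_equal(res$evaluated_count, 32L)
  expect_true(all(is.na(res$gamma[ref_v < 6])))
})

test_that("classify_discrepancy splits failures by dose sign", {
  ref_v <- random_dose_field(10, base = 40, seed = 5)
  ref <- dose_grid(ref_v, 3)
  over <- compute_gamma(ref, dose_grid(ref_v * 1.10, 3),
                        gamma_criteria(2, 2, norm_dose = 40))
  m_over <- classify_discrepancy(over)
  expect_true(any(m_over$over))
  expect_false(any(m_over$under))
  under <- compute_gamma(ref, dose_grid(ref_v * 0.90, 3),
                         gamma_criteria(2, 2, norm_dose = 40))
  m_under <- classify_discrepancy(under)
  expect_true(any(m_under$under))
  expect_false(any(m_under$over))
  ok <- compute_gamma(ref, ref, gamma_criteria(3, 3, norm_dose = 40))
  m_ok <- classify_discrepancy(ok)
  expect_false(any(m_ok$over) || any(m_ok$under))
})

test_that("pass_rate counts inclusively over evaluated points", {
  gam <- matrix(c(rep(0, 32), rep(1.2, 32)), 8, 8)
  fake <- structure(list(gamma = gam, signed_diff = gam * 0,
                         evaluated_count = 64L, pass_rate = 0.5,
                         criteria = gamma_criteria(3, 3, norm_dose = 1)),
                    class = "gamma_result")
  expect_equal(pass_rate(fake), 0.5)
  expect_equal(pass_rate(fake, 1.2), 1.0)
  gam0 <- matrix(0, 4, 4)
  fake0 <- structure(list(gamma = gam0, signed_diff = gam0,
                          evaluated_count = 16L, pass_rate = 1,
                          criteria = gamma_criteria(3, 3, norm_dose = 1)),
                     class = "gamma_result")
  expect_equal(pass_rate(fake0), 1.0)
})

test_that("the cumulative pixel-gamma histogram is consistent with the pass rate", {
  gam <- matrix(c(rep(0.5, 32), rep(1.5, 32)), 8, 8)
  fake <- structure(list(gamma = gam, signed_diff = gam * 0,
                         evaluated_count = 64L, pass_rate = 0.5,
                         criteria = gamma_criteria(3, 3, norm_dose = 1)),
                    class = "gamma_result")
  h <- pgh(fake)
  i1 <- which(abs(h$gamma_edges - 1.0) < 1e-9)
  expect_equal(h$cumulative_fraction[i1], pass_rate(fake))
  i15 <- which(abs(h$gamma_edges - 1.5) < 1e-9)
  expect_equal(h$cumulative_fraction[i15], 1.0)
  expect_true(all(diff(h$cumulative_fraction) >= 0))
  expect_equal(h$cumulative_fraction[length(h$cumulative_fraction)], 1.0)
  gam0 <- matrix(0, 4, 4)
  fake0 <- structure(list(gamma = gam0, signed_diff = gam0,
                          evaluated_count = 16L, pass_rate = 1,
                          criteria = gamma_criteria(3, 3, norm_dose = 1)),
                     class = "gamma_result")
  h0 <- pgh(fake0)
  expect_true(all(h0$cumulative_fraction == 1.0))
})

test_that("3D grids evaluate and slice into planes consistently", {
  arr <- array(50, c(6, 6, 4))
  arr[3, 3, 2] <- 55
  g3 <- dose_grid(arr, c(3, 3, 3))
  ax <- grid_plane(g3, "axial", 2)
  expect_equal(dim(ax$values), c(6L, 6L))
  expect_equal(ax$values[3, 3], 55)
  expect_error(grid_plane(ax, "axial", 1), "3D")
  res3 <- compute_gamma(g3, g3, gamma_criteria(3, 3, norm_dose = 50,
                                               upsample = 4L))
  expect_equal(max(res3$gamma), 0)
})
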