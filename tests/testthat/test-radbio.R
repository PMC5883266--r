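cord <- organ_model("spinal_cord", "serial", d50 = 66.5, gamma50 = 4, a = 20,
                    endpoint = "necrosis")
target50 <- organ_model("target", "target", d50 = 50, gamma50 = 2, a = -10)

test_that("organ_model validates its parameters", {
  expect_error(organ_model("x", "serial", d50 = -5, gamma50 = 4, a = 20), "> 0")
  expect_error(organ_model("x", "serial", d50 = 50, gamma50 = 0, a = 20), "> 0")
  expect_error(organ_model("x", "serial", d50 = 50, gamma50 = 4, a = 0),
               "non-zero")
  expect_error(organ_model("x", "target", d50 = 50, gamma50 = 2, a = 5),
               "a < 0")
})

test_that("EUD reduces to the generalized mean of the differential DVH", {
  uni <- dvh(c(40, 40.001), c(1, 0), kind = "differential")
  for (a in c(-10, -1, 0.5, 1, 8, 20))
    expect_equal(eud(uni, a), 40, tolerance = 1e-6)
  x <- dvh(c(10, 20), c(0.5, 0.5), kind = "differential")
  expect_equal(eud(x, 1), mean_dose(x), tolerance = 1e-12)
  expect_equal(eud(x, 2), sqrt(250), tolerance = 1e-12)
  expect_error(eud(x, 0), "non-zero")
})

test_that("EUD with a < 0 and cold volume returns the zero limit with a warning", {
  cold <- dvh(c(0, 30), c(0.1, 0.9), kind = "differential")
  expect_warning(res <- eud(cold, -10), "cold-spot")
  expect_equal(res, 0)
  # with a > 0 zero-dose bins contribute nothing but cause no warning
  expect_silent(hot <- eud(cold, 2))
  expect_equal(hot, (0.9 * 30^2)^(1 / 2), tolerance = 1e-12)
})

test_that("EUD is numerically stable and monotone in a", {
  for (seed in 1:25) {
    x <- random_dvh(seed)
    as_grid <- c(-10, -5, -2, -0.5, 0.5, 1, 2, 5, 10, 15, 20)
    vals <- vapply(as_grid, function(a) eud(x, a), numeric(1))
    expect_true(all(diff(vals) >= -1e-9))        # power-mean monotonicity
    expect_true(all(is.finite(vals)))
    expect_gte(min(vals), min(x$dose) - 1e-9)
    expect_lte(max(vals), max(x$dose) + 1e-9)
  }
})

test_that("TCP and NTCP are 0.5 exactly at their half-effect dose", {
  expect_equal(tcp(50, target50), 0.5, tolerance = 1e-12)
  expect_equal(ntcp(66.5, cord), 0.5, tolerance = 1e-12)
  expect_equal(tcp(0, target50), 0)
  expect_equal(ntcp(0, cord), 0)
  expect_error(tcp(50, cord), "target")
  expect_error(ntcp(50, target50), "serial or parallel")
})

test_that("logistic response matches direct high-precision evaluation", {
  # 1 / (1 + (50/55)^8)
  expect_equal(tcp(55, target50), 1 / (1 + (50 / 55)^8), tolerance = 1e-12)
  expect_equal(round(tcp(55, target50), 4), 0.6819)
  expect_equal(ntcp(49.9, cord), 0.010, tolerance = 1e-3)
  # strictly increasing in EUD
  euds <- seq(10, 90, by = 5)
  expect_true(all(diff(vapply(euds, ntcp, numeric(1), model = cord)) > 0))
  expect_true(all(diff(vapply(euds, tcp, numeric(1), model = target50)) > 0))
})

test_that("eud_for_probability inverts the response model", {
  expect_equal(eud_for_probability(0.5, cord), 66.5, tolerance = 1e-12)
  expect_equal(round(eud_for_probability(0.01, cord), 1), 49.9)
  eso <- organ_model("esophagus", "serial", d50 = 51, gamma50 = 4, a = 2.27)
  expect_equal(round(eud_for_probability(0.05, eso), 1), 42.4)
  for (p in c(0.01, 0.05, 0.2, 0.5, 0.8, 0.99))
    expect_equal(ntcp(eud_for_probability(p, cord), cord), p,
                 tolerance = 1e-10)
  expect_error(eud_for_probability(0, cord), "\\(0, 1\\)")
  expect_error(eud_for_probability(1, cord), "\\(0, 1\\)")
})

test_that("derive_gamma50 recovers the slope from an iso-NTCP anchor", {
  expect_equal(derive_gamma50(66.5, 49.9, 0.01), 4.00, tolerance = 0.005)
  expect_equal(derive_gamma50(24.5, 13.9, 0.01), 2.03, tolerance = 0.005)
  g <- derive_gamma50(40, 20, 0.07)
  m <- organ_model("x", "serial", d50 = 40, gamma50 = g, a = 8)
  expect_equal(ntcp(20, m), 0.07, tolerance = 1e-12)
  expect_error(derive_gamma50(40, 40, 0.01), "degenerate")
  expect_error(derive_gamma50(40, 20, 0.5), "0.5")
})

test_that("eud_interval brackets the EUD over the literature a-range", {
  uni <- dvh(c(40, 40.001), c(1, 0), kind = "differential")
  iv <- eud_interval(uni, "serial")
  expect_equal(iv$low, iv$high, tolerance = 1e-6)
  x <- dvh(c(10, 20), c(0.5, 0.5), kind = "differential")
  ivs <- eud_interval(x, "serial")
  expect_equal(ivs$low, eud(x, 4), tolerance = 1e-12)
  expect_equal(ivs$high, eud(x, 15), tolerance = 1e-12)
  ivp <- eud_interval(x, "parallel")
  expect_gte(ivp$low, min(x$dose))
  expect_lte(ivp$high, max(x$dose))
  # monotonicity in a means interior a stay inside the interval
  for (a in seq(4, 15, by = 1))
    expect_true(eud(x, a) >= ivs$low - 1e-9 && eud(x, a) <= ivs$high + 1e-9)
  expect_error(eud_interval(x, "target"), "arg")
})

test_that("D98 <= EUD <= D2 across the clinically used exponent range", {
  for (seed in 1:30) {
    x <- random_clinical_dvh(seed)
    d98 <- dose_at_volume(x, 0.98)
    d2 <- dose_at_volume(x, 0.02)
    for (a in c(-10, -3, -1, 0.5, 1, 3, 10, 20)) {
      e <- eud(x, a)
      expect_gte(e, d98 - 1e-6)
      expect_lte(e, d2 + 1e-6)
    }
  }
})

test_that("the bundled parameter table reproduces its iso-NTCP EUD columns", {
  tab <- organ_parameters()
  oar <- tab[tab$organ_class != "target", ]
  for (i in seq_len(nrow(oar))) {
    m <- organ_model(oar$organ[i], oar$organ_class[i], d50 = oar$d50[i],
                     gamma50 = oar$gamma50[i], a = oar$a[i])
    e1 <- eud_for_probability(0.01, m)
    e5 <- eud_for_probability(0.05, m)
    # every cell within 0.15 Gy of the printed value
    expect_lt(abs(e1 - oar$eud_max_1pct[i]), 0.15)
    expect_lt(abs(e5 - oar$eud_max_5pct[i]), 0.15)
  }
  # spinal cord and acute esophagitis reproduce at one-decimal rounding
  sc <- default_organ_model("spinal_cord")
  expect_equal(round(eud_for_probability(0.01, sc), 1), 49.9)
  expect_equal(round(eud_for_probability(0.05, sc), 1), 55.3)
  ee <- default_organ_model("esophagus_esophagitis")
  expect_equal(round(eud_for_probability(0.05, ee), 1), 42.4)
})

test_that("check_dose_limits evaluates classic limits and the EUD class", {
  lung <- default_organ_model("lung_pneumonitis")
  limits <- default_dose_limits()
  # a lung DVH with Dmean 14 Gy passes the conservative 15 Gy bound
  lungdvh <- dvh(c(13.999, 14.001), c(0.5, 0.5), kind = "differential",
                 structure = "lung")
  rep_lung <- check_dose_limits(lungdvh, limits$lung_pneumonitis, lung)
  expect_true(all(rep_lung$limits$pass))
  # conservative = FALSE uses the 20 Gy end of the range
  d18 <- dvh(c(17.999, 18.001), c(0.5, 0.5), kind = "differential")
  expect_false(all(check_dose_limits(d18, limits$lung_pneumonitis,
                                     lung)$limits$pass))
  expect_true(all(check_dose_limits(d18, limits$lung_pneumonitis, lung,
                                    conservative = FALSE)$limits$pass))
  # a cord DVH with D2% = 52 Gy fails the D2% < 50 Gy limit
  sc <- default_organ_model("spinal_cord")
  corddvh <- dvh(c(0, 52, 52.2), c(1, 0.021, 0), kind = "cumulative")
  rep_cord <- check_dose_limits(corddvh, limits$spinal_cord, sc)
  expect_false(all(rep_cord$limits$pass))
  # zero-dose structure passes everything
  zero <- dvh(c(0, 0.01), c(1, 0), kind = "cumulative")
  rep_zero <- check_dose_limits(zero, limits$spinal_cord, sc)
  expect_true(all(rep_zero$limits$pass))
  expect_equal(rep_zero$eud_class, "ntcp_le_1pct")
})
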