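make_beams <- function(mus) data.frame(beam_id = sprintf("B%d", seq_along(mus)),
                                       mu = mus)

simple_plan <- function(label, mus, dvhs = list(), grid = NULL, dpr = 60,
                        diso = 60, algorithm = "ref") {
  plan_record(label = label, algorithm = algorithm, dpr = dpr, diso = diso,
              beams = make_beams(mus), dvhs = dvhs, dose_grid = grid)
}

steep_ptv <- make_sigmoid_dvh("PTV", d50_gy = 60, steepness = 4)
models <- list(PTV = default_organ_model("target"))

test_that("delta_mu follows the plan1-minus-plan2 sign convention", {
  p1 <- simple_plan("plan1", c(100, 100))
  p2 <- simple_plan("plan2", c(104, 104), algorithm = "new")
  dm <- delta_mu(p1, p2)
  expect_equal(dm$total, -8)
  expect_equal(dm$total_pct, -4.0)
  expect_equal(dm$per_beam$delta, c(-4, -4))
  same <- delta_mu(p1, p1)
  expect_equal(same$total, 0)
  expect_true(all(same$per_beam$delta == 0))
  p3 <- simple_plan("plan2", c(90, 90))
  expect_gt(delta_mu(p1, p3)$total, 0)
  bad <- plan_record("plan2", "new", 60, 60,
                     data.frame(beam_id = c("X1", "X2"), mu = c(90, 90)))
  expect_error(delta_mu(p1, bad), "beam ids")
})

test_that("plan 3 rescales plan 2 by the monitor-unit transfer", {
  dvhs <- list(PTV = steep_ptv)
  p1 <- simple_plan("plan1", c(100, 100), dvhs = dvhs)
  p2 <- simple_plan("plan2", c(104, 104), dvhs = dvhs, algorithm = "new")
  p3 <- build_plan3(p1, p2)
  k <- 200 / 208
  expect_equal(p3$diso, 60 * k, tolerance = 1e-12)
  expect_equal(round(p3$diso, 2), 57.69)
  expect_equal(p3$dvhs$PTV$dose, steep_ptv$dose * k)
  expect_equal(p3$beams$mu, p1$beams$mu)
  # delta MU < 0 (plan 2 needs more MUs) => plan 3 delivers less dose
  expect_lt(p3$diso, p1$diso)
  # identical MUs leave plan 2 unchanged
  p2same <- simple_plan("plan2", c(100, 100), dvhs = dvhs, algorithm = "new")
  p3same <- build_plan3(p1, p2same)
  expect_equal(p3same$diso, p2same$diso)
  expect_equal(p3same$dvhs$PTV$dose, p2same$dvhs$PTV$dose)
  # no dose data at all is an error
  expect_error(build_plan3(p1, simple_plan("plan2", c(104, 104))),
               "no dose data")
})

test_that("plan 3 isocentre ratio equals the total MU ratio", {
  for (seed in 1:5) {
    set.seed(seed)
    mus1 <- runif(6, 80, 120)
    mus2 <- mus1 * runif(6, 0.95, 1.1)
    p1 <- simple_plan("plan1", mus1, dvhs = list(PTV = steep_ptv))
    p2 <- simple_plan("plan2", mus2, dvhs = list(PTV = steep_ptv))
    p3 <- build_plan3(p1, p2)
    expect_equal(p3$diso / p1$diso, sum(mus1) / sum(mus2),
                 tolerance = 1e-12)
  }
})

test_that("dvh_delta_report computes per-structure metric deltas", {
  dvhs <- list(PTV = steep_ptv,
               lung = make_sigmoid_dvh("lung", 12, 0.3))
  p1 <- simple_plan("plan1", c(100, 100), dvhs = dvhs)
  same <- dvh_delta_report(p1, p1, models)
  expect_true(all(abs(same$table$delta) < 1e-12))
  expect_equal(same$flagged, "lung")       # lung has no model supplied
  # a 3% global rescale moves every dose-type metric by exactly -3%
  p097 <- p1
  p097$dvhs <- lapply(dvhs, scale_dose, k = 0.97)
  rep97 <- dvh_delta_report(p1, p097, models)
  dose_rows <- rep97$table$metric %in% c("D98", "D2", "Dmean", "D95", "EUD") &
    rep97$table$ref > 0
  expect_equal(rep97$table$delta_pct[dose_rows],
               rep(-3, sum(dose_rows)), tolerance = 1e-9)
  # EUD moves with D95 under scaling (both decrease)
  tcp_row <- rep97$table$metric == "TCP"
  expect_true(all(rep97$table$delta[tcp_row] < 0))
  expect_error(dvh_delta_report(p1, simple_plan("plan2", c(1, 1))),
               "no structures")
})

test_that("the D95 screening flag uses a strict 2% tolerance", {
  p1 <- simple_plan("plan1", c(100, 100), dvhs = list(PTV = steep_ptv))
  shifted <- function(k) {
    p <- simple_plan("plan2", c(100, 100),
                     dvhs = list(PTV = scale_dose(steep_ptv, k)))
    p
  }
  expect_equal(d95_adjustment_flag(p1, shifted(1.01), "PTV")$flag,
               "no_adjustment")
  expect_equal(d95_adjustment_flag(p1, shifted(0.96), "PTV")$flag,
               "consider_adjustment")
  # exactly at the tolerance counts as actionable
  expect_equal(d95_adjustment_flag(p1, shifted(1.02), "PTV")$flag,
               "consider_adjustment")
  expect_error(d95_adjustment_flag(p1, shifted(1), "GTV"), "missing")
})

fragment <- function(p, d95, gpr, eud3, dpr = 60) {
  list(stats = list(p_value = p), d95_delta_pct = d95,
       gamma_pass_rates = gpr, dpr = dpr,
       plan3_target_eud = eud3, plan3_target_d95 = eud3)
}

test_that("recommend_prescription applies the decision tree", {
  keep <- recommend_prescription(fragment(0.6, 1, c(0.96, 0.99), 59.5))
  expect_equal(keep$outcome, "keep_dpr")
  expect_equal(keep$suggested_dpr, 60)
  # significant difference with plan 3 EUD of 55: -8.3%, inside the band
  adj <- recommend_prescription(fragment(0.01, 1, c(0.99, 0.99), 55))
  expect_equal(adj$outcome, "consider_adjustment")
  expect_equal(adj$suggested_dpr, 55)
  expect_equal(adj$change_pct, -100 * 5 / 60, tolerance = 1e-12)
  expect_true(adj$in_cited_band)
  # 58 Gy: -3.3%, flagged below the 5-10% band
  small <- recommend_prescription(fragment(0.01, 1, c(0.99, 0.99), 58))
  expect_equal(small$suggested_dpr, 58)
  expect_false(small$in_cited_band)
  # missing statistics
  ins <- recommend_prescription(fragment(NA, 1, NULL, 55))
  expect_equal(ins$outcome, "insufficient_evidence")
  # actionable finding but no plan-3 dose to suggest
  ins2 <- recommend_prescription(fragment(0.01, 5, NULL, NA))
  expect_equal(ins2$outcome, "insufficient_evidence")
})

test_that("the decision is monotone: worsening inputs never rescues keep_dpr", {
  base <- fragment(0.6, 1, c(0.97), 57)
  expect_equal(recommend_prescription(base)$outcome, "keep_dpr")
  worse_p <- fragment(0.01, 1, c(0.97), 57)
  worse_d95 <- fragment(0.6, 4, c(0.97), 57)
  worse_gamma <- fragment(0.6, 1, c(0.90), 57)
  for (w in list(worse_p, worse_d95, worse_gamma))
    expect_equal(recommend_prescription(w)$outcome, "consider_adjustment")
  # and once adjusting, worsening further never flips back
  all_bad <- fragment(0.001, 6, c(0.80), 57)
  expect_equal(recommend_prescription(all_bad)$outcome,
               "consider_adjustment")
})

test_that("compare_plans assembles the full report", {
  sc <- transition_scenario(dpr = 60, global_scale = 0.95, noise_sd = 0.4,
                            seed = 11)
  pair <- make_plan_pair(sc, m_beams = 8L, shape = c(16L, 16L))
  rep <- compare_plans(pair$plan1, pair$plan2, pair$models)
  expect_s3_class(rep, "transition_report")
  expect_equal(rep$plan3$diso / rep$plan1$diso,
               sum(rep$plan1$beams$mu) / sum(rep$plan2$beams$mu),
               tolerance = 1e-12)
  expect_lt(rep$stats$p_value, 0.05)
  expect_equal(rep$decision$outcome, "consider_adjustment")
  expect_equal(length(rep$gamma_pass_rates), 2L)
  expect_true(all(c("dvh_deltas_plan2", "dvh_deltas_plan3") %in% names(rep)))
  out <- capture.output(print(rep))
  expect_true(any(grepl("decision_outcome", out)))
})
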