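#' Treatment-plan records for the plan 1/2/3 comparison
#'
#' A `plan_record` carries everything the QA workflow needs from one plan:
#' the algorithm label, dose-reporting mode, prescription dose, dose at the
#' isocentre, per-beam monitor units, per-structure DVHs, and optionally a
#' dose grid. Plan 1 is the reference plan (old algorithm), plan 2 the
#' recalculation with the new algorithm at the same prescription, and plan
#' 3 the new-algorithm recalculation using plan 1's monitor units.
#'
#' @param label `"plan1"`, `"plan2"` or `"plan3"`.
#' @param algorithm free-text algorithm name (e.g. `"AAA"`, `"AXB-Dmm"`).
#' @param dpr prescription dose in Gy (> 0).
#' @param diso dose at the isocentre in Gy (> 0).
#' @param beams data.frame with columns `beam_id` (unique) and `mu` (> 0).
#' @param dvhs named list of [dvh] objects, one per structure.
#' @param dose_grid optional [dose_grid].
#' @param dose_mode `"Dw"` (dose-to-water) or `"Dm"` (dose-to-medium).
#' @return An object of class `plan_record`.
#' @export
plan_record <- function(label = c("plan1", "plan2", "plan3"),
                        algorithm, dpr, diso, beams,
                        dvhs = list(), dose_grid = NULL,
                        dose_mode = c("Dw", "Dm")) {
  label <- match.arg(label)
  dose_mode <- match.arg(dose_mode)
  stopifnot_scalar_number(dpr, "dpr", positive = TRUE)
  stopifnot_scalar_number(diso, "diso", positive = TRUE)
  if (!is.data.frame(beams) || !all(c("beam_id", "mu") %in% names(beams)))
    ds_validation_error("'beams' must be a data.frame with beam_id and mu")
  if (anyDuplicated(beams$beam_id))
    ds_validation_error("duplicate beam_id in 'beams'")
  if (any(beams$mu <= 0) || anyNA(beams$mu))
    ds_validation_error("all beam MUs must be > 0")
  if (length(dvhs) && (is.null(names(dvhs)) || any(!nzchar(names(dvhs)))))
    ds_validation_error("'dvhs' must be a named list keyed by structure")
  for (d in dvhs) stopifnot(inherits(d, "dvh"))
  if (!is.null(dose_grid)) stopifnot(inherits(dose_grid, "dose_grid"))
  structure(
    list(label = label, algorithm = as.character(algorithm)[1L],
         dose_mode = dose_mode, dpr = dpr, diso = diso,
         beams = data.frame(beam_id = as.character(beams$beam_id),
                            mu = as.numeric(beams$mu)),
         dvhs = dvhs, dose_grid = dose_grid),
    class = "plan_record"
  )
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf("<plan_record> %s: %s (%s), Dpr %.4g Gy, Diso %.4g Gy, %d beams (%.1f MU), %d structures%s\n",
              x$label, x$algorithm, x$dose_mode, x$dpr, x$diso,
              nrow(x$beams), sum(x$beams$mu), length(x$dvhs),
              if (is.null(x$dose_grid)) "" else ", dose grid"))
  invisible(x)
}

#' Decision rules for the prescription-adjustment test
#'
#' The tolerances the decision engine applies: the D95% delta below which no
#' adjustment is needed (strict inequality: a delta exactly at the
#' tolerance is actionable), the gamma criteria list and pass-rate goal,
#' and the significance level of the paired test.
#'
#' @param d95_tolerance_percent D95% tolerance in percent (default 2).
#' @param gamma_criteria_list list of [gamma_criteria] (default 2%/2 mm and
#'   3%/3 mm, global).
#' @param gamma_pass_goal minimal acceptable pass rate (default 0.95).
#' @param alpha significance level (default 0.05).
#' @return An object of class `decision_rules`.
#' @export
decision_rules <- function(d95_tolerance_percent = 2,
                           gamma_criteria_list = list(gamma_criteria(2, 2),
                                                      gamma_criteria(3, 3)),
                           gamma_pass_goal = 0.95, alpha = 0.05) {
  stopifnot_scalar_number(d95_tolerance_percent, "d95_tolerance_percent",
                          positive = TRUE)
  stopifnot_scalar_number(gamma_pass_goal, "gamma_pass_goal", positive = TRUE)
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  if (gamma_pass_goal > 1) ds_domain_error("'gamma_pass_goal' must be <= 1")
  for (g in gamma_criteria_list) stopifnot(inherits(g, "gamma_criteria"))
  structure(
    list(d95_tolerance_percent = d95_tolerance_percent,
         gamma_criteria_list = gamma_criteria_list,
         gamma_pass_goal = gamma_pass_goal, alpha = alpha),
    class = "decision_rules"
  )
}

#' Monitor-unit differences between two plans
#'
#' Per-beam and total `MU(plan1) - MU(plan2)`, absolute and as a percentage
#' of plan 1. The sign convention follows the delivered-dose reasoning:
#' a positive total delta (reference plan needed more MUs) means the
#' isocentre dose of plan 3 will be *higher* than in plan 1.
#'
#' @param plan1 reference [plan_record].
#' @param plan2 tested [plan_record]; must carry the same beam ids.
#' @return An object of class `delta_mu`: list with `per_beam` (data.frame
#'   beam_id, mu1, mu2, delta, delta_pct), `total`, `total_pct`.
#' @export
delta_mu <- function(plan1, plan2) {
  stopifnot(inherits(plan1, "plan_record"), inherits(plan2, "plan_record"))
  b1 <- plan1$beams; b2 <- plan2$beams
  if (!setequal(b1$beam_id, b2$beam_id))
    ds_validation_error("plans do not share the same beam ids")
  b2 <- b2[match(b1$beam_id, b2$beam_id), ]
  delta <- b1$mu - b2$mu
  structure(
    list(per_beam = data.frame(beam_id = b1$beam_id, mu1 = b1$mu,
                               mu2 = b2$mu, delta = delta,
                               delta_pct = 100 * delta / b1$mu),
         total = sum(delta),
         total_pct = 100 * sum(delta) / sum(b1$mu)),
    class = "delta_mu"
  )
}

#' @export
print.delta_mu <- function(x, ...) {
  cat(sprintf("<delta_mu> total %.2f MU (%.2f%% of plan 1) over %d beams\n",
              x$total, x$total_pct, nrow(x$per_beam)))
  invisible(x)
}

#' Emulate plan 3 (new algorithm with plan 1's monitor units)
#'
#' Plan 3 is the new algorithm's recalculation of the treatment using
#' exactly plan 1's monitor units. Without a planning system it is emulated
#' by linear rescaling: dose is proportional to MU for fixed geometry, so
#' every dose quantity of plan 2 is multiplied by
#' `k = sum(MU plan1) / sum(MU plan2)`. Plan 3 therefore shows the dose the
#' historical plans actually delivered as seen by the new algorithm.
#'
#' @param plan1 reference [plan_record].
#' @param plan2 tested [plan_record] carrying DVHs (and optionally a dose
#'   grid) computed by the new algorithm.
#' @return A [plan_record] with label `"plan3"`.
#' @export
build_plan3 <- function(plan1, plan2) {
  stopifnot(inherits(plan1, "plan_record"), inherits(plan2, "plan_record"))
  if (length(plan2$dvhs) == 0L && is.null(plan2$dose_grid))
    ds_validation_error("plan 2 carries no dose data (DVHs or dose grid)")
  dm <- delta_mu(plan1, plan2)
  k <- sum(dm$per_beam$mu1) / sum(dm$per_beam$mu2)
  dvhs3 <- lapply(plan2$dvhs, scale_dose, k = k)
  grid3 <- plan2$dose_grid
  if (!is.null(grid3)) grid3$values <- grid3$values * k
  plan_record(
    label = "plan3", algorithm = plan2$algorithm, dpr = plan2$dpr,
    diso = plan2$diso * k,
    beams = plan1$beams, dvhs = dvhs3, dose_grid = grid3,
    dose_mode = plan2$dose_mode
  )
}

#' Per-structure DVH and radiobiology deltas between two plans
#'
#' For every structure present in both plans, computes D98%, D2%, Dmean,
#' D95%, V95% and -- where an organ model is supplied -- EUD and TCP
#' (targets) or NTCP (organs at risk), in both plans, with absolute and
#' percent deltas (test minus reference). Structures without a model get a
#' metrics-only row and are listed in `flagged`.
#'
#' @param ref reference [plan_record].
#' @param test tested [plan_record].
#' @param models named list of [organ_model] keyed by structure name
#'   (may be empty for a metrics-only report).
#' @return List with `table` (data.frame structure, metric, ref, test,
#'   delta, delta_pct) and `flagged` (structures lacking a model).
#' @export
dvh_delta_report <- function(ref, test, models = list()) {
  stopifnot(inherits(ref, "plan_record"), inherits(test, "plan_record"))
  shared <- intersect(names(ref$dvhs), names(test$dvhs))
  if (length(shared) == 0L)
    ds_validation_error("plans share no structures")
  rows <- list()
  flagged <- character()
  for (s in shared) {
    mr <- dvh_metrics(ref$dvhs[[s]], dpr = ref$dpr)
    mt <- dvh_metrics(test$dvhs[[s]], dpr = ref$dpr)
    model <- models[[s]]
    if (!is.null(model)) {
      er <- eud(ref$dvhs[[s]], model$a)
      et <- eud(test$dvhs[[s]], model$a)
      mr <- c(mr, EUD = er)
      mt <- c(mt, EUD = et)
      if (model$organ_class == "target") {
        mr <- c(mr, TCP = tcp(er, model)); mt <- c(mt, TCP = tcp(et, model))
      } else {
        mr <- c(mr, NTCP = ntcp(er, model)); mt <- c(mt, NTCP = ntcp(et, model))
      }
    } else if (length(models)) {
      flagged <- c(flagged, s)
    }
    rows[[s]] <- data.frame(
      structure = s, metric = names(mr), ref = unname(mr),
      test = unname(mt), delta = unname(mt - mr),
      delta_pct = ifelse(mr != 0, 100 * unname(mt - mr) / unname(mr), NA_real_)
    )
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       flagged = flagged)
}

#' Target-coverage adjustment flag from the D95% delta
#'
#' The screening rule on target coverage: if the target D95% of the tested
#' plan agrees with the reference within the tolerance (default 2%,
#' strict), no adjustment is needed; otherwise an adjustment of the
#' prescription is to be considered. A delta exactly at the tolerance is
#' treated as actionable.
#'
#' @param ref,test [plan_record]s exposing the target structure's DVH.
#' @param target name of the target structure in both plans' DVH sets.
#' @param rules a [decision_rules].
#' @return List with `flag` (`"no_adjustment"` or `"consider_adjustment"`)
#'   and `d95_delta_pct`.
#' @export
d95_adjustment_flag <- function(ref, test, target,
                                rules = decision_rules()) {
  stopifnot(inherits(rules, "decision_rules"))
  if (!target %in% names(ref$dvhs) || !target %in% names(test$dvhs))
    ds_validation_error(sprintf("target '%s' missing from a plan", target))
  d95r <- dose_at_volume(ref$dvhs[[target]], 0.95)
  d95t <- dose_at_volume(test$dvhs[[target]], 0.95)
  delta_pct <- 100 * (d95t - d95r) / d95r
  # strict boundary (a delta at the tolerance is actionable), with a tiny
  # epsilon so a delta sitting on the boundary up to round-off still trips
  flag <- if (abs(delta_pct) < rules$d95_tolerance_percent - 1e-9)
    "no_adjustment" else "consider_adjustment"
  list(flag = flag, d95_delta_pct = delta_pct)
}

#' Prescription-adjustment decision
#'
#' The decision tree applied after the full comparison: the prescription is
#' kept when the paired test finds no significant difference (p at or above
#' alpha), the target D95% delta is within tolerance, and every gamma
#' comparison meets the pass-rate goal. Otherwise an adjustment is
#' recommended, with the suggested new prescription set to plan 3's target
#' EUD -- the realistic delivered dose of the historical plans as seen by
#' the new algorithm -- reported with its percent change; changes whose
#' magnitude falls in the 5--10% band typical of major algorithm-generation
#' transitions are flagged. Missing inputs yield `insufficient_evidence`.
#'
#' @param report a [transition_report][compare_plans] (or a list exposing
#'   `stats$p_value`, `d95_delta_pct`, `gamma_pass_rates`,
#'   `plan3_target_eud`, `dpr`).
#' @param rules a [decision_rules].
#' @param use_d95 suggest plan 3's target D95% instead of its EUD (the EUD
#'   is the default because it is the quantity tied to tumour control).
#' @return An object of class `decision_outcome`: list with `outcome`
#'   (`"keep_dpr"`, `"consider_adjustment"`, `"insufficient_evidence"`),
#'   `suggested_dpr`, `change_pct`, `in_cited_band`, `reasons`.
#' @export
recommend_prescription <- function(report, rules = decision_rules(),
                                   use_d95 = FALSE) {
  stopifnot(inherits(rules, "decision_rules"))
  p <- report$stats$p_value
  d95 <- report$d95_delta_pct
  gpr <- report$gamma_pass_rates
  dpr <- report$dpr
  sugg <- if (use_d95) report$plan3_target_d95 else report$plan3_target_eud
  if (is.null(p) || is.null(d95) || is.null(dpr) ||
      length(p) == 0L || is.na(p) || is.na(d95)) {
    return(structure(
      list(outcome = "insufficient_evidence", suggested_dpr = NA_real_,
           change_pct = NA_real_, in_cited_band = NA,
           reasons = "missing statistics or DVH inputs"),
      class = "decision_outcome"
    ))
  }
  reasons <- character()
  if (p < rules$alpha)
    reasons <- c(reasons,
                 sprintf("significant paired difference (p = %.3g < %.2g)",
                         p, rules$alpha))
  if (abs(d95) >= rules$d95_tolerance_percent - 1e-9)
    reasons <- c(reasons,
                 sprintf("target D95%% shifted by %.2f%% (tolerance %.2g%%)",
                         d95, rules$d95_tolerance_percent))
  if (!is.null(gpr) && length(gpr) && any(gpr < rules$gamma_pass_goal))
    reasons <- c(reasons,
                 sprintf("gamma pass rate below %.0f%% goal (%s)",
                         100 * rules$gamma_pass_goal,
                         paste(sprintf("%.1f%%", 100 * gpr[gpr < rules$gamma_pass_goal]),
                               collapse = ", ")))
  if (length(reasons) == 0L) {
    return(structure(
      list(outcome = "keep_dpr", suggested_dpr = dpr, change_pct = 0,
           in_cited_band = FALSE, reasons = "no actionable difference"),
      class = "decision_outcome"
    ))
  }
  if (is.null(sugg) || is.na(sugg)) {
    return(structure(
      list(outcome = "insufficient_evidence", suggested_dpr = NA_real_,
           change_pct = NA_real_, in_cited_band = NA,
           reasons = c(reasons, "plan 3 target dose unavailable")),
      class = "decision_outcome"
    ))
  }
  change_pct <- 100 * (sugg - dpr) / dpr
  structure(
    list(outcome = "consider_adjustment", suggested_dpr = sugg,
         change_pct = change_pct,
         in_cited_band = abs(change_pct) >= 5 && abs(change_pct) <= 10,
         reasons = reasons),
    class = "decision_outcome"
  )
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat("<decision_outcome>", x$outcome, "\n")
  if (x$outcome == "consider_adjustment") {
    cat(sprintf("  suggested Dpr: %.2f Gy (%+.1f%%)%s\n",
                x$suggested_dpr, x$change_pct,
                if (isTRUE(x$in_cited_band))
                  " [within the 5-10% band typical of major transitions]"
                else " [outside the typical 5-10% band]"))
  }
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Full plan 1 vs plan 2 transition comparison
#'
#' Runs the complete QA workflow on a reference plan and its
#' new-algorithm recalculation: monitor-unit accounting, emulation of plan
#' 3, DVH-index and radiobiology deltas (plan 1 vs plan 2 and plan 1 vs
#' plan 3), gamma comparison of the dose grids under each configured
#' criteria set, paired Wilcoxon and Spearman statistics on the beam
#' monitor units, and the prescription-adjustment decision.
#'
#' @param plan1 reference [plan_record].
#' @param plan2 tested [plan_record] (same prescription, new algorithm).
#' @param models named list of [organ_model] keyed by structure; the entry
#'   with `organ_class == "target"` identifies the target structure.
#' @param rules a [decision_rules].
#' @return An object of class `transition_report`.
#' @export
compare_plans <- function(plan1, plan2, models = list(),
                          rules = decision_rules()) {
  stopifnot(inherits(plan1, "plan_record"), inherits(plan2, "plan_record"))
  dm <- delta_mu(plan1, plan2)
  plan3 <- build_plan3(plan1, plan2)

  deltas2 <- if (length(intersect(names(plan1$dvhs), names(plan2$dvhs))))
    dvh_delta_report(plan1, plan2, models) else NULL
  deltas3 <- if (length(intersect(names(plan1$dvhs), names(plan3$dvhs))))
    dvh_delta_report(plan1, plan3, models) else NULL

  target <- NULL
  for (s in names(models))
    if (models[[s]]$organ_class == "target") target <- s
  d95_delta_pct <- NA_real_
  plan3_target_eud <- NA_real_
  plan3_target_d95 <- NA_real_
  if (!is.null(target) && target %in% names(plan1$dvhs) &&
      target %in% names(plan2$dvhs)) {
    d95 <- d95_adjustment_flag(plan1, plan2, target, rules)
    d95_delta_pct <- d95$d95_delta_pct
    plan3_target_eud <- eud(plan3$dvhs[[target]], models[[target]]$a)
    plan3_target_d95 <- dose_at_volume(plan3$dvhs[[target]], 0.95)
  }

  gamma_results <- NULL
  gamma_pass_rates <- NULL
  if (!is.null(plan1$dose_grid) && !is.null(plan2$dose_grid)) {
    gamma_results <- lapply(rules$gamma_criteria_list, function(cr) {
      if (is.null(cr$norm_dose) && cr$normalization == "global")
        cr$norm_dose <- plan1$diso
      compute_gamma(plan1$dose_grid, plan2$dose_grid, cr)
    })
    names(gamma_results) <- vapply(gamma_results,
                                   function(g) format(g$criteria), "")
    gamma_pass_rates <- vapply(gamma_results, function(g) g$pass_rate,
                               numeric(1))
  }

  mu_sample <- paired_sample(dm$per_beam$mu1, dm$per_beam$mu2, unit = "MU")
  d <- mu_sample$test - mu_sample$reference
  stats <- if (all(d == 0)) {
    list(p_value = 1, statistic = NA_real_, n_used = 0L,
         rho = if (length(d) >= 3L &&
                   length(unique(mu_sample$reference)) > 1L)
           spearman_rho(mu_sample) else NA_real_,
         note = "all MU differences zero; no signed-rank test possible")
  } else {
    w <- wilcoxon_signed_rank(mu_sample)
    rho <- if (length(d) >= 3L &&
               length(unique(mu_sample$reference)) > 1L &&
               length(unique(mu_sample$test)) > 1L)
      spearman_rho(mu_sample) else NA_real_
    list(p_value = w$p_value, statistic = w$statistic, n_used = w$n_used,
         rho = rho, note = NULL)
  }

  report <- structure(
    list(plan1 = plan1, plan2 = plan2, plan3 = plan3,
         dpr = plan1$dpr,
         delta_mu = dm,
         dvh_deltas_plan2 = deltas2, dvh_deltas_plan3 = deltas3,
         gamma_results = gamma_results, gamma_pass_rates = gamma_pass_rates,
         stats = stats,
         target = target, d95_delta_pct = d95_delta_pct,
         plan3_target_eud = plan3_target_eud,
         plan3_target_d95 = plan3_target_d95,
         rules = rules),
    class = "transition_report"
  )
  report$decision <- recommend_prescription(report, rules)
  report
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report> %s -> %s (Dpr %.4g Gy)\n",
              x$plan1$algorithm, x$plan2$algorithm, x$dpr))
  cat(sprintf("  delta MU: %+.2f (%+.2f%%); plan 3 Diso %.3f Gy (plan 1: %.3f Gy)\n",
              x$delta_mu$total, x$delta_mu$total_pct,
              x$plan3$diso, x$plan1$diso))
  if (!is.na(x$d95_delta_pct))
    cat(sprintf("  target '%s' D95%% delta (plan 2 vs 1): %+.2f%%; plan 3 target EUD %.2f Gy\n",
                x$target, x$d95_delta_pct, x$plan3_target_eud))
  if (!is.null(x$gamma_pass_rates))
    for (nm in names(x$gamma_pass_rates))
      cat(sprintf("  gamma %s: pass rate %.1f%%\n", nm,
                  100 * x$gamma_pass_rates[[nm]]))
  cat(sprintf("  Wilcoxon on beam MUs: p = %.4g%s\n", x$stats$p_value,
              if (is.na(x$stats$rho)) "" else
                sprintf(", Spearman rho = %.3f", x$stats$rho)))
  print(x$decision)
  invisible(x)
}

#' @export
summary.transition_report <- function(object, ...) {
  print(object)
  if (!is.null(object$dvh_deltas_plan3)) {
    cat("\nPlan 1 vs plan 3 per-structure deltas:\n")
    print(object$dvh_deltas_plan3$table, digits = 4)
  }
  invisible(object)
}

#' @export
plot.transition_report <- function(x, ...) {
  if (is.null(x$gamma_results) || length(x$gamma_results) == 0L) {
    graphics::plot.new()
    graphics::title("no gamma results to plot")
    return(invisible(x))
  }
  h <- pgh(x$gamma_results[[1L]])
  plot(h, main = sprintf("Pixel-gamma histogram, %s",
                         names(x$gamma_results)[1L]), ...)
  invisible(x)
}
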