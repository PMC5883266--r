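#' Radiobiological organ model
#'
#' Parameter set for the EUD-based logistic dose-response models: the
#' half-effect dose `d50` (TCD50 for targets, TD50 for organs at risk), the
#' normalized slope `gamma50` of the dose-response curve at its midpoint,
#' and the volume-effect exponent `a` (negative for tumours, where cold
#' spots dominate; around 1 for parallel organs such as lung; large for
#' serial organs such as spinal cord, where hot spots dominate; `a = 1/n`
#' in Lyman-Kutcher-Burman notation).
#'
#' @param name organ/structure name.
#' @param organ_class `"target"`, `"serial"` or `"parallel"`.
#' @param d50 half-effect dose in Gy (> 0).
#' @param gamma50 unitless slope (> 0).
#' @param a volume-effect exponent (non-zero; must be negative for targets).
#' @param endpoint clinical endpoint label.
#' @return An object of class `organ_model`.
#' @examples
#' cord <- organ_model("spinal cord", "serial", d50 = 66.5, gamma50 = 4,
#'                     a = 20, endpoint = "necrosis")
#' eud_for_probability(0.01, cord)  # 49.9 Gy
#' @export
organ_model <- function(name, organ_class = c("target", "serial", "parallel"),
                        d50, gamma50, a, endpoint = "") {
  organ_class <- match.arg(organ_class)
  stopifnot_scalar_number(d50, "d50", positive = TRUE)
  stopifnot_scalar_number(gamma50, "gamma50", positive = TRUE)
  stopifnot_scalar_number(a, "a")
  if (a == 0)
    ds_domain_error("'a' must be non-zero")
  if (organ_class == "target" && a >= 0)
    ds_domain_error("target models require a < 0 (cold spots dominate)")
  structure(
    list(name = as.character(name)[1L], organ_class = organ_class,
         d50 = d50, gamma50 = gamma50, a = a,
         endpoint = as.character(endpoint)[1L]),
    class = "organ_model"
  )
}

#' @export
print.organ_model <- function(x, ...) {
  cat(sprintf("<organ_model> %s (%s): %s%.4g Gy, gamma50 = %.3g, a = %.3g%s\n",
              x$name, x$organ_class,
              if (x$organ_class == "target") "TCD50 = " else "TD50 = ",
              x$d50, x$gamma50, x$a,
              if (nzchar(x$endpoint)) paste0(", endpoint: ", x$endpoint) else ""))
  invisible(x)
}

#' Equivalent uniform dose (EUD)
#'
#' Niemierko's generalized-mean EUD of a dose-volume histogram:
#' `EUD = (sum_i v_i D_i^a)^(1/a)`, where `v_i` is the fractional volume
#' receiving dose `D_i` and `a` is the tissue-specific volume-effect
#' exponent. `a = 1` gives the mean dose; large positive `a` approaches the
#' near-maximum dose (D2%), large negative `a` the near-minimum dose (D98%).
#'
#' Computed on the differential form with zero-volume bins dropped, via
#' logarithms with max-dose factoring for stability at large `|a|`. For
#' `a < 0` with non-zero volume at zero dose the mathematical limit 0 is
#' returned with a warning (a single cold voxel annihilates the
#' generalized mean).
#'
#' @param x a [dvh].
#' @param a volume-effect exponent, non-zero.
#' @return EUD in Gy.
#' @examples
#' x <- dvh(c(10, 20), c(0.5, 0.5), kind = "differential")
#' eud(x, 1)   # 15, the mean dose
#' eud(x, 2)   # sqrt(250)
#' @export
eud <- function(x, a) {
  stopifnot(inherits(x, "dvh"))
  stopifnot_scalar_number(a, "a")
  if (a == 0)
    ds_domain_error("'a' must be non-zero (the a -> 0 geometric-mean limit is not used)")
  dx <- as_differential(x)
  keep <- dx$volume > 0
  v <- dx$volume[keep]
  d <- dx$dose[keep]
  if (length(v) == 0L) return(0)
  v <- v / sum(v)
  if (any(d == 0)) {
    if (a < 0) {
      warning("zero-dose volume with a < 0: EUD is 0 (cold-spot limit)")
      return(0)
    }
    v <- v[d > 0]
    d <- d[d > 0]
    if (length(d) == 0L) return(0)
  }
  dmax <- max(d)
  # log-sum-exp of log(v) + a*log(d/dmax), then back out the dmax factor
  w <- log(v) + a * log(d / dmax)
  m <- max(w)
  dmax * exp((m + log(sum(exp(w - m)))) / a)
}

logistic_response <- function(eud_value, d50, gamma50) {
  if (eud_value == 0) return(0)
  1 / (1 + exp(4 * gamma50 * (log(d50) - log(eud_value))))
}

#' Logistic TCP and NTCP dose-response models
#'
#' Tumour control probability and normal-tissue complication probability as
#' logistic functions of EUD:
#' `TCP = 1 / (1 + (TCD50 / EUD)^(4 gamma50))` and
#' `NTCP = 1 / (1 + (TD50 / EUD)^(4 gamma50))`.
#' At `EUD = d50` both equal exactly 0.5; `gamma50` sets the normalized
#' slope there. `tcp()` requires a target model, `ntcp()` an organ-at-risk
#' (serial or parallel) model.
#'
#' @param eud_value EUD in Gy (`>= 0`); `0` returns probability 0.
#' @param model an [organ_model].
#' @return Probability in `[0, 1]`.
#' @export
tcp <- function(eud_value, model) {
  stopifnot(inherits(model, "organ_model"))
  stopifnot_scalar_number(eud_value, "eud_value")
  if (eud_value < 0) ds_domain_error("'eud_value' must be >= 0")
  if (model$organ_class != "target")
    ds_domain_error("tcp() requires a target model")
  logistic_response(eud_value, model$d50, model$gamma50)
}

#' @rdname tcp
#' @export
ntcp <- function(eud_value, model) {
  stopifnot(inherits(model, "organ_model"))
  stopifnot_scalar_number(eud_value, "eud_value")
  if (eud_value < 0) ds_domain_error("'eud_value' must be >= 0")
  if (!model$organ_class %in% c("serial", "parallel"))
    ds_domain_error("ntcp() requires a serial or parallel organ model")
  logistic_response(eud_value, model$d50, model$gamma50)
}

#' Invert the logistic dose-response model
#'
#' The EUD that yields a given response probability:
#' `EUD = d50 / (1/p - 1)^(1 / (4 gamma50))`. This is how iso-NTCP dose
#' limits (e.g. the EUD giving NTCP of 1% or 5%) are derived from
#' `(d50, gamma50)`.
#'
#' @param p probability in (0, 1).
#' @param model an [organ_model].
#' @return EUD in Gy; `ntcp()`/`tcp()` of the result recovers `p`.
#' @export
eud_for_probability <- function(p, model) {
  stopifnot(inherits(model, "organ_model"))
  stopifnot_scalar_number(p, "p")
  if (p <= 0 || p >= 1)
    ds_domain_error("'p' must lie strictly in (0, 1)")
  model$d50 / (1 / p - 1)^(1 / (4 * model$gamma50))
}

#' Recover the slope gamma50 from one (dose, response) anchor
#'
#' Given the half-effect dose `d50` and one EUD known to produce response
#' probability `p`, inverts the logistic model for the slope:
#' `gamma50 = ln(1/p - 1) / (4 ln(d50 / eud_value))`. Useful when a
#' parameter table prints iso-NTCP EUD columns but omits the slope.
#'
#' @param d50 half-effect dose in Gy.
#' @param eud_value EUD in Gy producing response `p` (different from `d50`).
#' @param p probability in (0, 1), different from 0.5.
#' @return The slope gamma50.
#' @export
derive_gamma50 <- function(d50, eud_value, p) {
  stopifnot_scalar_number(d50, "d50", positive = TRUE)
  stopifnot_scalar_number(eud_value, "eud_value", positive = TRUE)
  stopifnot_scalar_number(p, "p")
  if (p <= 0 || p >= 1 || p == 0.5)
    ds_domain_error("'p' must lie in (0, 1) and differ from 0.5")
  if (eud_value == d50)
    ds_domain_error("'eud_value' equal to 'd50' is degenerate (any slope fits)")
  log(1 / p - 1) / (4 * log(d50 / eud_value))
}

#' EUD confidence interval over a volume-effect exponent range
#'
#' When `a` cannot be calibrated for an organ, an interval around the EUD is
#' obtained by evaluating it at the endpoints of the literature range of
#' `a`: 0.5--3.0 for parallel organs, 4.0--15.0 for serial organs. EUD is a
#' generalized power mean, hence non-decreasing in `a`, so the endpoints
#' bound the interval.
#'
#' @param x a [dvh].
#' @param organ_class `"parallel"` or `"serial"` (no interval is defined for
#'   targets).
#' @return An object of class `eud_interval`: list with `low`, `high` (Gy)
#'   and the exponents `a_low`, `a_high` used.
#' @export
eud_interval <- function(x, organ_class = c("parallel", "serial")) {
  organ_class <- match.arg(organ_class)
  rng <- if (organ_class == "parallel") c(0.5, 3.0) else c(4.0, 15.0)
  lo <- eud(x, rng[1L])
  hi <- eud(x, rng[2L])
  structure(
    list(low = min(lo, hi), high = max(lo, hi),
         a_low = rng[1L], a_high = rng[2L], organ_class = organ_class),
    class = "eud_interval"
  )
}

#' @export
print.eud_interval <- function(x, ...) {
  cat(sprintf("<eud_interval> %s organ: [%.3f, %.3f] Gy (a in [%g, %g])\n",
              x$organ_class, x$low, x$high, x$a_low, x$a_high))
  invisible(x)
}

#' Bundled organ parameter table
#'
#' Returns the packaged radiobiological parameter table for lung-treatment
#' planning objectives: per organ the model class, `d50`, volume-effect
#' exponent `a`, slope `gamma50`, endpoint, and the EUD ceilings
#' corresponding to NTCP of 1% and 5%. The printed source table omits
#' `gamma50`; the bundled values were derived by inverting the 1% EUD
#' column (see the `gamma50_provenance` column), which reproduces the
#' spinal-cord and acute-esophagitis cells at one-decimal rounding and the
#' remaining organs to within 0.15 Gy.
#'
#' @return A data.frame, one row per organ entry.
#' @export
organ_parameters <- function() {
  path <- system.file("extdata", "organ_parameters.tsv", package = "doseshift")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname organ_parameters
#' @param organ name of a row of [organ_parameters()].
#' @return `default_organ_model()` returns the corresponding [organ_model].
#' @export
default_organ_model <- function(organ) {
  tab <- organ_parameters()
  row <- tab[tab$organ == organ, , drop = FALSE]
  if (nrow(row) != 1L)
    ds_domain_error(sprintf("unknown organ '%s'; see organ_parameters()$organ", organ))
  organ_model(row$organ, row$organ_class, d50 = row$d50,
              gamma50 = row$gamma50, a = row$a, endpoint = row$endpoint)
}

#' Dose-limit records and compliance checking
#'
#' `dose_limit_record()` bundles an organ's EUD ceilings (iso-NTCP 1% and
#' 5%) with its classic DVH dose limits (comparator on Dmean, D2%, D98%,
#' D95% or V95%). `default_dose_limits()` returns the packaged limits for
#' the lung-treatment organ set. `check_dose_limits()` evaluates a DVH
#' against a record: every classic limit is tested (ranges such as
#' "15--20 Gy" use the conservative lower bound by default) and the
#' structure's EUD is classified against the 1%/5% ceilings.
#'
#' @param organ organ name.
#' @param eud_max_1pct,eud_max_5pct EUD ceilings in Gy
#'   (`eud_max_1pct < eud_max_5pct`); `NA` allowed for targets.
#' @param classic_limits data.frame with columns `metric` (one of `Dmean`,
#'   `D2`, `D98`, `D95`, `V95`), `cmp` (`"lt"`, `"le"`, `"gt"`, `"ge"`),
#'   `value`, optional `value_high` (for range limits) and `relative`
#'   (logical: value is a fraction of the prescription dose).
#' @return `dose_limit_record()`: an object of class `dose_limit_record`.
#' @export
dose_limit_record <- function(organ, eud_max_1pct = NA, eud_max_5pct = NA,
                              classic_limits = NULL) {
  if (!is.na(eud_max_1pct) && !is.na(eud_max_5pct) &&
      eud_max_1pct >= eud_max_5pct)
    ds_validation_error("eud_max_1pct must be < eud_max_5pct")
  if (!is.null(classic_limits)) {
    need <- c("metric", "cmp", "value")
    if (!all(need %in% names(classic_limits)))
      ds_validation_error("classic_limits needs columns metric, cmp, value")
    if (is.null(classic_limits$value_high)) classic_limits$value_high <- NA_real_
    if (is.null(classic_limits$relative)) classic_limits$relative <- FALSE
  }
  structure(
    list(organ = organ, eud_max_1pct = eud_max_1pct,
         eud_max_5pct = eud_max_5pct, classic_limits = classic_limits),
    class = "dose_limit_record"
  )
}

#' @rdname dose_limit_record
#' @export
default_dose_limits <- function() {
  path <- system.file("extdata", "dose_limits.tsv", package = "doseshift")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  par <- organ_parameters()
  out <- lapply(split(tab, tab$organ), function(g) {
    p <- par[par$organ == g$organ[1L], , drop = FALSE]
    dose_limit_record(
      organ = g$organ[1L],
      eud_max_1pct = if (nrow(p)) p$eud_max_1pct else NA,
      eud_max_5pct = if (nrow(p)) p$eud_max_5pct else NA,
      classic_limits = g[, c("metric", "cmp", "value", "value_high", "relative")]
    )
  })
  out
}

#' @rdname dose_limit_record
#' @param x a [dvh] to check.
#' @param record a `dose_limit_record`.
#' @param model the structure's [organ_model] (for the EUD classification).
#' @param dpr prescription dose in Gy; needed for relative and V95 limits.
#' @param conservative use the lower bound of range limits (default `TRUE`).
#' @return `check_dose_limits()`: an object of class `compliance_report`
#'   with a per-limit pass/fail table and the EUD classification.
#' @export
check_dose_limits <- function(x, record, model, dpr = NULL,
                              conservative = TRUE) {
  stopifnot(inherits(x, "dvh"), inherits(record, "dose_limit_record"),
            inherits(model, "organ_model"))
  metrics <- dvh_metrics(x, dpr = dpr)
  limits <- record$classic_limits
  tab <- NULL
  if (!is.null(limits) && nrow(limits)) {
    obs <- thr <- pass <- numeric(nrow(limits))
    for (i in seq_len(nrow(limits))) {
      m <- limits$metric[i]
      if (!m %in% names(metrics))
        ds_validation_error(sprintf(
          "metric '%s' not computable (V95 needs dpr)", m))
      obs[i] <- metrics[[m]]
      v <- limits$value[i]
      if (!conservative && !is.na(limits$value_high[i]))
        v <- limits$value_high[i]
      if (isTRUE(limits$relative[i])) {
        if (is.null(dpr))
          ds_validation_error("relative dose limit needs dpr")
        v <- v * dpr
      }
      thr[i] <- v
      pass[i] <- switch(limits$cmp[i],
        lt = obs[i] < v, le = obs[i] <= v,
        gt = obs[i] > v, ge = obs[i] >= v,
        ds_validation_error(sprintf("unknown comparator '%s'", limits$cmp[i])))
    }
    tab <- data.frame(metric = limits$metric, cmp = limits$cmp,
                      observed = obs, threshold = thr,
                      pass = as.logical(pass))
  }
  eud_val <- eud(x, model$a)
  eud_class <- if (!is.na(record$eud_max_1pct) && eud_val <= record$eud_max_1pct) {
    "ntcp_le_1pct"
  } else if (!is.na(record$eud_max_5pct) && eud_val <= record$eud_max_5pct) {
    "ntcp_le_5pct"
  } else if (is.na(record$eud_max_5pct)) {
    "no_eud_ceiling"
  } else {
    "exceeds_5pct"
  }
  structure(
    list(organ = record$organ, limits = tab, eud = eud_val,
         eud_class = eud_class,
         all_pass = is.null(tab) || all(tab$pass)),
    class = "compliance_report"
  )
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %s: EUD %.2f Gy (%s)\n",
              x$organ, x$eud, x$eud_class))
  if (!is.null(x$limits)) print(x$limits)
  cat(if (x$all_pass) "all classic limits pass\n" else "classic limit violation\n")
  invisible(x)
}
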