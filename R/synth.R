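# Synthetic plan/grid/DVH/MU generators. The "new algorithm" effect is
# modelled as a global multiplicative dose scale plus a localized additive
# perturbation (emulating heterogeneity-driven disagreement, e.g. in lung),
# with a systematic monitor-unit shift: the statistical signature the QA
# workflow must detect. No radiation transport is simulated.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Algorithm-transition scenario
#'
#' Parameter set describing how a simulated "new" algorithm differs from
#' the reference: a global multiplicative dose scale (e.g. 0.97 when the
#' new algorithm computes 3% less dose for the same monitor units), an
#' optional localized additive perturbation (centre/radius in mm,
#' amplitude in Gy), a systematic monitor-unit shift in percent (defaults
#' to the value consistent with the dose scale,
#' `100 * (1/global_scale - 1)`, since re-normalising plan 2 to the same
#' prescription requires proportionally more monitor units), and per-beam
#' MU noise.
#'
#' @param dpr prescription dose in Gy.
#' @param global_scale multiplicative dose shift of the new algorithm
#'   (> 0; 1 = no systematic shift).
#' @param local_perturbation `NULL`, or a list with `center_mm` (physical
#'   coordinates), `radius_mm` (> 0) and `amplitude_gy`.
#' @param mu_shift_percent systematic MU difference of plan 2 relative to
#'   plan 1 in percent; `NULL` derives it from `global_scale`.
#' @param noise_sd standard deviation of per-beam MU noise (>= 0).
#' @param seed integer seed driving every random draw.
#' @return An object of class `transition_scenario`.
#' @export
transition_scenario <- function(dpr = 60, global_scale = 0.97,
                                local_perturbation = NULL,
                                mu_shift_percent = NULL, noise_sd = 0,
                                seed = 1L) {
  stopifnot_scalar_number(dpr, "dpr", positive = TRUE)
  stopifnot_scalar_number(global_scale, "global_scale", positive = TRUE)
  if (noise_sd < 0) ds_domain_error("'noise_sd' must be >= 0")
  if (is.null(mu_shift_percent))
    mu_shift_percent <- 100 * (1 / global_scale - 1)
  if (!is.null(local_perturbation)) {
    need <- c("center_mm", "radius_mm", "amplitude_gy")
    if (!all(need %in% names(local_perturbation)))
      ds_validation_error(
        "local_perturbation needs center_mm, radius_mm, amplitude_gy")
    if (local_perturbation$radius_mm <= 0)
      ds_validation_error("perturbation radius must be > 0")
  }
  structure(
    list(dpr = dpr, global_scale = global_scale,
         local_perturbation = local_perturbation,
         mu_shift_percent = mu_shift_percent, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "transition_scenario"
  )
}

#' @export
print.transition_scenario <- function(x, ...) {
  cat(sprintf("<transition_scenario> Dpr %.4g Gy, scale %.4g, MU shift %+.2f%%, noise sd %.3g, seed %d%s\n",
              x$dpr, x$global_scale, x$mu_shift_percent, x$noise_sd, x$seed,
              if (is.null(x$local_perturbation)) ""
              else sprintf(", perturbation %+.2g Gy (r = %g mm)",
                           x$local_perturbation$amplitude_gy,
                           x$local_perturbation$radius_mm)))
  invisible(x)
}

grid_axis_coords <- function(shape, spacing, origin) {
  lapply(seq_along(shape),
         function(ax) origin[ax] + (seq_len(shape[ax]) - 1L) * spacing[ax])
}

#' Synthetic phantom dose grid
#'
#' A stand-in for a planning-system dose export: a circular (2D) or
#' spherical (3D) high-dose region at the prescription dose centred in the
#' grid, with a smooth Gaussian penumbra falloff outside the flat core.
#' Deterministic for a given seed.
#'
#' @param shape integer vector of grid dimensions (2 or 3 entries).
#' @param spacing_mm per-axis spacing in mm (scalar recycled).
#' @param dpr prescription (core) dose in Gy.
#' @param target_radius_mm radius of the flat core in mm; must fit inside
#'   the grid.
#' @param penumbra_sigma_mm Gaussian falloff scale of the penumbra in mm.
#' @param seed integer seed (kept for interface symmetry; the phantom is
#'   deterministic).
#' @return A [dose_grid].
#' @export
make_phantom_grid <- function(shape = c(32L, 32L), spacing_mm = 3,
                              dpr = 60, target_radius_mm = 20,
                              penumbra_sigma_mm = 8, seed = 1L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) ds_validation_error("'shape' must have 2 or 3 axes")
  spacing <- rep(as.numeric(spacing_mm), length.out = nd)
  stopifnot_scalar_number(dpr, "dpr", positive = TRUE)
  stopifnot_scalar_number(target_radius_mm, "target_radius_mm", positive = TRUE)
  stopifnot_scalar_number(penumbra_sigma_mm, "penumbra_sigma_mm", positive = TRUE)
  half_extent <- (shape - 1L) * spacing / 2
  if (target_radius_mm >= min(half_extent))
    ds_validation_error("target radius does not fit inside the grid")
  center <- half_extent
  ax <- grid_axis_coords(shape, spacing, rep(0, nd))
  r2 <- (ax[[1L]] - center[1L])^2
  for (k in seq_len(nd)[-1L])
    r2 <- outer(r2, (ax[[k]] - center[k])^2, "+")
  r <- sqrt(r2)
  v <- ifelse(r <= target_radius_mm, dpr,
              dpr * exp(-(r - target_radius_mm)^2 / (2 * penumbra_sigma_mm^2)))
  dose_grid(array(v, shape), spacing = spacing)
}

#' Apply a transition scenario to a dose grid or plan
#'
#' For a [dose_grid]: the dose the new algorithm computes *for the same
#' monitor units* -- every voxel scaled by `global_scale`, with the
#' localized perturbation added inside its region (a smooth compactly
#' supported bump). For a [plan_record] (the reference plan 1): the
#' matching plan 2 -- re-normalised to the same prescription, so the DVHs
#' are carried over, the beam monitor units are shifted by
#' `mu_shift_percent` plus per-beam noise, and the dose grid (if present)
#' is the new algorithm's grid re-normalised by `1 / global_scale`, which
#' leaves only the local perturbation as residual disagreement.
#'
#' @param x a [dose_grid] or [plan_record].
#' @param scenario a [transition_scenario].
#' @param ... unused.
#' @return An object of the same class as `x`.
#' @export
apply_transition <- function(x, scenario, ...) UseMethod("apply_transition")

perturbation_field <- function(grid, pert) {
  nd <- length(dim(grid$values))
  ctr <- pert$center_mm
  if (length(ctr) != nd)
    ds_validation_error("perturbation center dimensionality mismatch")
  ax <- grid_axis_coords(dim(grid$values), grid$spacing, grid$origin)
  for (k in seq_len(nd))
    if (ctr[k] < min(ax[[k]]) || ctr[k] > max(ax[[k]]))
      ds_validation_error("perturbation region lies outside the grid")
  r2 <- (ax[[1L]] - ctr[1L])^2
  for (k in seq_len(nd)[-1L])
    r2 <- outer(r2, (ax[[k]] - ctr[k])^2, "+")
  u <- pmin(sqrt(r2) / pert$radius_mm, 1)
  pert$amplitude_gy * (1 - u^2)^2
}

#' @rdname apply_transition
#' @export
apply_transition.dose_grid <- function(x, scenario, ...) {
  stopifnot(inherits(scenario, "transition_scenario"))
  v <- x$values * scenario$global_scale
  if (!is.null(scenario$local_perturbation))
    v <- v + perturbation_field(x, scenario$local_perturbation)
  if (any(v < 0)) {
    warning("perturbation drove doses negative; clipped at 0")
    v <- pmax(v, 0)
  }
  dose_grid(v, spacing = x$spacing, origin = x$origin)
}

#' @rdname apply_transition
#' @export
apply_transition.plan_record <- function(x, scenario, ...) {
  stopifnot(inherits(scenario, "transition_scenario"))
  mu2 <- with_seed(scenario$seed, {
    x$beams$mu * (1 + scenario$mu_shift_percent / 100) +
      stats::rnorm(nrow(x$beams), 0, scenario$noise_sd)
  })
  if (any(mu2 <= 0))
    ds_validation_error("scenario noise produced non-positive MUs")
  grid2 <- NULL
  if (!is.null(x$dose_grid)) {
    g <- apply_transition(x$dose_grid, scenario)
    g$values <- g$values / scenario$global_scale   # renormalized to same Dpr
    grid2 <- g
  }
  plan_record(
    label = "plan2", algorithm = "new", dpr = x$dpr, diso = x$diso,
    beams = data.frame(beam_id = x$beams$beam_id, mu = mu2),
    dvhs = x$dvhs, dose_grid = grid2, dose_mode = "Dm"
  )
}

#' Synthetic sigmoid DVH
#'
#' A parametric stand-in for a planning-system DVH: a cumulative DVH with
#' logistic falloff around `d50_gy`, `V(D) = 1 / (1 + exp(steepness * (D -
#' d50)))`, truncated where the tail becomes negligible. Large `steepness`
#' approaches a uniform dose at `d50_gy` (all EUDs converge to `d50_gy`).
#'
#' @param structure structure label.
#' @param d50_gy dose at which half the volume is covered (> 0).
#' @param steepness logistic slope in 1/Gy (> 0); larger is steeper.
#' @param bin_gy dose-bin width in Gy (default 0.05).
#' @param seed optional seed used only when `noise_sd > 0`.
#' @param noise_sd relative volume jitter (default 0: deterministic).
#' @return A cumulative [dvh].
#' @export
make_sigmoid_dvh <- function(structure, d50_gy, steepness, bin_gy = 0.05,
                             seed = 1L, noise_sd = 0) {
  stopifnot_scalar_number(d50_gy, "d50_gy", positive = TRUE)
  stopifnot_scalar_number(steepness, "steepness", positive = TRUE)
  stopifnot_scalar_number(bin_gy, "bin_gy", positive = TRUE)
  dmax <- d50_gy + 30 / steepness
  dose <- seq(0, dmax, by = bin_gy)
  v <- 1 / (1 + exp(steepness * (dose - d50_gy)))
  if (noise_sd > 0) {
    v <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0, noise_sd)))
    v <- rev(cummax(rev(pmin(pmax(v, 0), 1))))   # restore monotonicity
  }
  v[length(v)] <- 0
  dvh(dose, v, kind = "cumulative", structure = structure)
}

#' Synthetic paired monitor-unit sample
#'
#' Reference beam MUs drawn uniformly around 100 MU, with test MUs equal to
#' the reference shifted by `mu_shift_percent` plus Gaussian noise --
#' the paired structure the signed-rank bootstrap operates on.
#'
#' @param m_beams number of beams (>= 2).
#' @param mu_shift_percent systematic shift in percent.
#' @param noise_sd per-beam noise standard deviation in MU.
#' @param seed integer seed.
#' @param mu_range range of reference MUs (default 80--120).
#' @return A [paired_sample] with unit `"MU"`.
#' @export
make_paired_mu <- function(m_beams, mu_shift_percent = 0, noise_sd = 0,
                           seed = 1L, mu_range = c(80, 120)) {
  m_beams <- as.integer(m_beams)
  if (m_beams < 2L) ds_validation_error("'m_beams' must be >= 2")
  with_seed(seed, {
    ref <- stats::runif(m_beams, mu_range[1L], mu_range[2L])
    tst <- ref * (1 + mu_shift_percent / 100) +
      stats::rnorm(m_beams, 0, noise_sd)
    paired_sample(ref, tst, unit = "MU")
  })
}

#' Build a matched plan 1 / plan 2 pair from a scenario
#'
#' Assembles the full fixture for the workflow: plan 1 with seeded beam
#' MUs, sigmoid DVHs for a steep target (centred at the prescription), a
#' parallel lung and a serial spinal cord, and a phantom dose grid; plan 2
#' via [apply_transition()]. The returned `models` list carries the
#' matching [organ_model]s (target slope from the bundled table, organs at
#' risk from their bundled rows).
#'
#' @param scenario a [transition_scenario].
#' @param m_beams number of beams (default 10).
#' @param shape,spacing_mm phantom grid geometry (default 24 x 24 at 3 mm).
#' @param target_steepness logistic slope of the target DVH (default 4 /Gy,
#'   a tightly covered target).
#' @return List with `plan1`, `plan2`, `models`.
#' @export
make_plan_pair <- function(scenario, m_beams = 10L, shape = c(24L, 24L),
                           spacing_mm = 3, target_steepness = 4) {
  stopifnot(inherits(scenario, "transition_scenario"))
  mu1 <- with_seed(scenario$seed + 1L,
                   round(stats::runif(m_beams, 80, 120), 1))
  beams <- data.frame(beam_id = sprintf("B%02d", seq_len(m_beams)), mu = mu1)
  dpr <- scenario$dpr
  dvhs <- list(
    PTV = make_sigmoid_dvh("PTV", d50_gy = dpr, steepness = target_steepness),
    lung = make_sigmoid_dvh("lung", d50_gy = 0.2 * dpr, steepness = 0.25),
    spinal_cord = make_sigmoid_dvh("spinal_cord", d50_gy = 0.45 * dpr,
                                   steepness = 0.5)
  )
  grid <- make_phantom_grid(shape = shape, spacing_mm = spacing_mm,
                            dpr = dpr, target_radius_mm = 0.25 *
                              min((shape - 1L) * spacing_mm),
                            seed = scenario$seed)
  plan1 <- plan_record(label = "plan1", algorithm = "reference", dpr = dpr,
                       diso = dpr, beams = beams, dvhs = dvhs,
                       dose_grid = grid, dose_mode = "Dw")
  plan2 <- apply_transition(plan1, scenario)
  models <- list(
    PTV = default_organ_model("target"),
    lung = default_organ_model("lung_pneumonitis"),
    spinal_cord = default_organ_model("spinal_cord")
  )
  list(plan1 = plan1, plan2 = plan2, models = models)
}

#' Write a complete synthetic plan 1 / plan 2 dataset to disk
#'
#' Generates a plan pair from a scenario and writes both manifests (DVH
#' tables, MU tables and dose grids) into a directory, so the file-based
#' workflow can be exercised end to end.
#'
#' @param dir output directory.
#' @param scenario a [transition_scenario].
#' @param grid_format `"text"` or `"dicom"` for the dose grids.
#' @param ... passed to [make_plan_pair()].
#' @return Character vector with the two manifest paths.
#' @export
simulate_transition_dataset <- function(dir, scenario = transition_scenario(),
                                        grid_format = c("text", "dicom"),
                                        ...) {
  grid_format <- match.arg(grid_format)
  pair <- make_plan_pair(scenario, ...)
  c(write_plan_manifest(pair$plan1, dir, grid_format = grid_format),
    write_plan_manifest(pair$plan2, dir, grid_format = grid_format))
}
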