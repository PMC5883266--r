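#' Dose grid objects
#'
#' A regular 2D or 3D grid of absorbed dose with physical spacing. Grid
#' coordinates are physical millimetres with the origin at the centre of the
#' first voxel; axis order is fixed (slowest-varying axis = slice for 3D
#' grids read from file).
#'
#' @param values numeric matrix (2D) or 3D array of dose in Gy, all
#'   non-negative, at least 2 points per axis.
#' @param spacing numeric vector of per-axis step in mm (> 0), one entry per
#'   array dimension.
#' @param origin per-axis physical coordinate of the first voxel centre in
#'   mm (default all 0).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = NULL) {
  if (is.null(dim(values)))
    ds_validation_error("'values' must be a matrix or 3D array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L))
    ds_validation_error("dose grids must be 2D or 3D")
  if (any(dim(values) < 2L))
    ds_validation_error("dose grids need at least 2 points per axis")
  if (anyNA(values) || any(values < 0))
    ds_validation_error("doses must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd || any(spacing <= 0))
    ds_validation_error("'spacing' must be positive, one entry per axis")
  if (is.null(origin)) origin <- rep(0, nd)
  origin <- as.numeric(origin)
  if (length(origin) != nd)
    ds_validation_error("'origin' must have one entry per axis")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing %s mm, dose %.3g-%.3g Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

same_frame <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Gamma comparison criteria
#'
#' The acceptance criteria of the gamma index: a dose-difference criterion
#' `dd_percent` (percent of the normalization dose) and a
#' distance-to-agreement criterion `dta_mm` (mm) jointly define the
#' acceptance ellipse; a point passes when some nearby evaluated dose lies
#' inside it (gamma <= 1).
#'
#' @param dd_percent dose-difference criterion in percent (> 0).
#' @param dta_mm distance-to-agreement criterion in mm (> 0).
#' @param normalization `"global"` (percent of one normalization dose,
#'   conventionally the prescription/isocentre dose) or `"local"` (percent
#'   of the local reference dose).
#' @param norm_dose normalization dose in Gy for global mode; defaults to
#'   the reference grid maximum when omitted.
#' @param low_dose_cutoff_percent reference points below this percentage of
#'   the normalization dose are excluded from evaluation (default 0: all
#'   points evaluated).
#' @param search_cap_mm maximum search radius for the distance term
#'   (default `3 * dta_mm`).
#' @param upsample integer factor by which the evaluated grid is linearly
#'   interpolated for the distance search (default 10).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dd_percent = 3, dta_mm = 3,
                           normalization = c("global", "local"),
                           norm_dose = NULL, low_dose_cutoff_percent = 0,
                           search_cap_mm = 3 * dta_mm, upsample = 10L) {
  normalization <- match.arg(normalization)
  stopifnot_scalar_number(dd_percent, "dd_percent", positive = TRUE)
  stopifnot_scalar_number(dta_mm, "dta_mm", positive = TRUE)
  stopifnot_scalar_number(search_cap_mm, "search_cap_mm", positive = TRUE)
  if (search_cap_mm < dta_mm)
    ds_domain_error("'search_cap_mm' must be >= 'dta_mm'")
  if (low_dose_cutoff_percent < 0)
    ds_domain_error("'low_dose_cutoff_percent' must be >= 0")
  upsample <- as.integer(upsample)
  if (upsample < 1L) ds_domain_error("'upsample' must be >= 1")
  structure(
    list(dd_percent = dd_percent, dta_mm = dta_mm,
         normalization = normalization, norm_dose = norm_dose,
         low_dose_cutoff_percent = low_dose_cutoff_percent,
         search_cap_mm = search_cap_mm, upsample = upsample),
    class = "gamma_criteria"
  )
}

#' @export
format.gamma_criteria <- function(x, ...) {
  sprintf("%g%%/%g mm (%s)", x$dd_percent, x$dta_mm, x$normalization)
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat("<gamma_criteria>", format(x), "\n")
  invisible(x)
}

# linear-interpolation expansion matrix: maps n samples to (n-1)*f + 1
interp_matrix <- function(n, f) {
  m <- (n - 1L) * f + 1L
  j <- seq_len(m) - 1L
  i0 <- pmin(j %/% f + 1L, n - 1L)
  w <- j / f - (i0 - 1L)
  W <- matrix(0, m, n)
  W[cbind(seq_len(m), i0)] <- 1 - w
  W[cbind(seq_len(m), i0 + 1L)] <- W[cbind(seq_len(m), i0 + 1L)] + w
  W
}

upsample_grid <- function(values, f) {
  if (f == 1L) return(values)
  d <- dim(values)
  if (length(d) == 2L) {
    W1 <- interp_matrix(d[1L], f)
    W2 <- interp_matrix(d[2L], f)
    return(W1 %*% values %*% t(W2))
  }
  W1 <- interp_matrix(d[1L], f)
  W2 <- interp_matrix(d[2L], f)
  m1 <- nrow(W1); m2 <- nrow(W2)
  slices <- lapply(seq_len(d[3L]), function(k) W1 %*% values[, , k] %*% t(W2))
  W3 <- interp_matrix(d[3L], f)
  m3 <- nrow(W3)
  out <- array(0, c(m1, m2, m3))
  for (j in seq_len(m3)) {
    nz <- which(W3[j, ] != 0)
    acc <- W3[j, nz[1L]] * slices[[nz[1L]]]
    if (length(nz) > 1L) acc <- acc + W3[j, nz[2L]] * slices[[nz[2L]]]
    out[, , j] <- acc
  }
  out
}

#' Gamma-index comparison of two dose grids
#'
#' For every evaluated reference point r, gamma is the minimum over nearby
#' positions e of the evaluated distribution of
#' `sqrt(((D_e(e) - D_r(r)) / dD)^2 + (|e - r| / dta)^2)`,
#' with `dD` the dose-difference criterion in Gy (global: percent of the
#' normalization dose; local: percent of the local reference dose) and the
#' evaluated dose linearly interpolated between grid points. `gamma <= 1`
#' means the point satisfies the criteria.
#'
#' Both grids must share the physical frame (dimensions, spacing, origin);
#' resample beforehand if they do not. Grids that look noisy (Monte-Carlo
#' style dose grids) inflate or deflate gamma; a high-frequency
#' coefficient-of-variation heuristic emits a warning in that case, no
#' correction is applied.
#'
#' @param ref reference [dose_grid].
#' @param eval_grid evaluated (tested) [dose_grid].
#' @param criteria a [gamma_criteria].
#' @return An object of class `gamma_result`: list with `gamma` (array of
#'   gamma values, `NA` at excluded points), `signed_diff` (evaluated minus
#'   reference at each point), `evaluated_count`, `pass_rate`, `criteria`.
#' @examples
#' g <- dose_grid(matrix(10, 8, 8), spacing = c(3, 3))
#' res <- compute_gamma(g, g, gamma_criteria(3, 3, norm_dose = 10))
#' res$pass_rate  # 1
#' @export
compute_gamma <- function(ref, eval_grid, criteria = gamma_criteria()) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_grid, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  if (!same_frame(ref, eval_grid))
    ds_validation_error("grids do not share a physical frame; resample first")
  nd <- length(dim(ref$values))
  norm <- criteria$norm_dose
  if (is.null(norm)) norm <- max(ref$values)
  if (criteria$normalization == "global" && norm <= 0)
    ds_validation_error("normalization dose must be > 0")
  warn_if_noisy(ref$values)
  warn_if_noisy(eval_grid$values)

  f <- criteria$upsample
  fine <- upsample_grid(eval_grid$values, f)
  fs <- ref$spacing / f                     # fine step per axis
  fdim <- dim(fine)
  if (is.null(fdim)) fdim <- dim(ref$values)

  # window half-width in fine steps per axis, capped by the search radius
  hw <- pmax(1L, as.integer(floor(criteria$search_cap_mm / fs)))
  offs <- lapply(seq_len(nd), function(ax) (-hw[ax]:hw[ax]) * fs[ax])
  dist2 <- offs[[1L]]^2
  for (ax in seq_len(nd)[-1L])
    dist2 <- outer(dist2, offs[[ax]]^2, "+")
  dta2 <- criteria$dta_mm^2

  rdim <- dim(ref$values)
  gam <- array(NA_real_, rdim)
  cutoff <- criteria$low_dose_cutoff_percent / 100 * norm
  idx_grid <- arrayInd(seq_along(ref$values), rdim)
  for (p in seq_along(ref$values)) {
    dr <- ref$values[p]
    if (dr < cutoff) next
    if (criteria$normalization == "local") {
      if (dr <= 0) next
      dd_abs <- criteria$dd_percent / 100 * dr
    } else {
      dd_abs <- criteria$dd_percent / 100 * norm
    }
    ci <- (idx_grid[p, ] - 1L) * f + 1L     # fine index of this ref point
    lo <- pmax(ci - hw, 1L)
    hi <- pmin(ci + hw, fdim)
    if (nd == 2L) {
      w <- fine[lo[1L]:hi[1L], lo[2L]:hi[2L], drop = FALSE]
      d2 <- dist2[(lo[1L]:hi[1L]) - ci[1L] + hw[1L] + 1L,
                  (lo[2L]:hi[2L]) - ci[2L] + hw[2L] + 1L, drop = FALSE]
    } else {
      w <- fine[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
      d2 <- dist2[(lo[1L]:hi[1L]) - ci[1L] + hw[1L] + 1L,
                  (lo[2L]:hi[2L]) - ci[2L] + hw[2L] + 1L,
                  (lo[3L]:hi[3L]) - ci[3L] + hw[3L] + 1L, drop = FALSE]
    }
    gam[p] <- sqrt(min((w - dr)^2 / dd_abs^2 + d2 / dta2))
  }

  evaluated <- sum(!is.na(gam))
  if (evaluated == 0L)
    ds_validation_error("no reference points were evaluated (cutoff too high?)")
  res <- structure(
    list(gamma = gam,
         signed_diff = eval_grid$values - ref$values,
         evaluated_count = evaluated,
         pass_rate = mean(gam[!is.na(gam)] <= 1 + 1e-9),
         criteria = criteria),
    class = "gamma_result"
  )
  res
}

warn_if_noisy <- function(values, ratio_threshold = 1.2,
                          amplitude_threshold = 0.005) {
  # Monte-Carlo-like noise heuristic: for white noise the second
  # difference is sqrt(3) times as variable as the first difference,
  # while smooth fields have a much smaller ratio. Only flagged when the
  # fluctuation amplitude is non-negligible relative to the grid mean.
  if (length(dim(values)) != 2L) return(invisible(FALSE))
  d1 <- diff(values)
  d2 <- diff(values, differences = 2L)
  s1 <- stats::sd(d1); s2 <- stats::sd(d2)
  m <- mean(values[values > 0])
  if (is.finite(s1) && s1 > 0 && is.finite(m) && m > 0 &&
      s2 / s1 > ratio_threshold && s2 / m > amplitude_threshold) {
    warning(sprintf(paste0(
      "dose grid shows white-noise-like high-frequency fluctuation ",
      "(second/first difference ratio %.2f); gamma statistics are ",
      "unreliable on noisy (Monte-Carlo-like) grids"), s2 / s1))
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: %d points evaluated, pass rate %.1f%% (gamma <= 1)\n",
              format(x$criteria), x$evaluated_count, 100 * x$pass_rate))
  invisible(x)
}

#' Gamma pass rate
#'
#' Fraction of evaluated points with gamma at or below a threshold
#' (inclusive: points at exactly the threshold pass). Plans are
#' conventionally considered equivalent when at least 95% of points pass at
#' gamma <= 1.
#'
#' @param result a [gamma_result].
#' @param gamma_threshold threshold (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
pass_rate <- function(result, gamma_threshold = 1.0) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$gamma[!is.na(result$gamma)]
  if (length(g) == 0L)
    ds_validation_error("no evaluated points")
  # inclusive boundary: a point at exactly the threshold passes (compared
  # with a 1e-9 absolute tolerance so round-off cannot demote it)
  mean(g <= gamma_threshold + 1e-9)
}

#' Cumulative pixel-gamma histogram
#'
#' The fraction of evaluated points with gamma at or below each bin edge, a
#' cumulative histogram whose value at edge 1.0 equals the pass rate.
#'
#' @param result a [gamma_result].
#' @param bin_width gamma bin width (default 0.1).
#' @return An object of class `pgamma_histogram`: list with `gamma_edges`
#'   and `cumulative_fraction` (non-decreasing, ending at 1).
#' @export
pgh <- function(result, bin_width = 0.1) {
  stopifnot(inherits(result, "gamma_result"))
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  g <- result$gamma[!is.na(result$gamma)]
  if (length(g) == 0L)
    ds_validation_error("no evaluated points")
  k <- max(ceiling(max(g) / bin_width), ceiling(1 / bin_width))
  edges <- (0:k) * bin_width
  cf <- vapply(edges, function(e) mean(g <= e + 1e-9), numeric(1))
  structure(list(gamma_edges = edges, cumulative_fraction = cf),
            class = "pgamma_histogram")
}

#' @export
print.pgamma_histogram <- function(x, ...) {
  i1 <- which.min(abs(x$gamma_edges - 1))
  cat(sprintf("<pgamma_histogram> %d edges to gamma = %.2g; fraction at gamma <= 1: %.3f\n",
              length(x$gamma_edges), max(x$gamma_edges),
              x$cumulative_fraction[i1]))
  invisible(x)
}

#' @export
plot.pgamma_histogram <- function(x, ...) {
  graphics::plot(x$gamma_edges, x$cumulative_fraction, type = "s",
                 xlab = expression(gamma), ylab = "cumulative fraction",
                 ylim = c(0, 1), ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}

#' Classify failing gamma points by sign of the dose discrepancy
#'
#' Splits the points with gamma > 1 into an overestimate mask (evaluated
#' dose above reference) and an underestimate mask (below), the
#' red/blue classification used on gamma maps to show where a new algorithm
#' raises or lowers the dose.
#'
#' @param result a [gamma_result].
#' @return List with logical arrays `over` and `under` (same shape as the
#'   gamma map; `FALSE` at excluded points).
#' @export
classify_discrepancy <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  fail <- !is.na(result$gamma) & result$gamma > 1
  list(over = fail & result$signed_diff > 0,
       under = fail & result$signed_diff < 0)
}

#' Extract a 2D plane from a 3D dose grid
#'
#' Per-plane gamma evaluation (axial / sagittal / coronal) works on 2D
#' slices of a 3D grid; this helper pulls one out with the correct spacing
#' and origin. Axis order of 3D grids is (row, column, slice); axial slices
#' fix the slice index, coronal the row, sagittal the column.
#'
#' @param grid a 3D [dose_grid].
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param index slice index along the fixed axis.
#' @return A 2D [dose_grid].
#' @export
grid_plane <- function(grid, plane = c("axial", "coronal", "sagittal"),
                       index) {
  stopifnot(inherits(grid, "dose_grid"))
  plane <- match.arg(plane)
  d <- dim(grid$values)
  if (length(d) != 3L)
    ds_domain_error("grid_plane() needs a 3D grid")
  ax <- switch(plane, axial = 3L, coronal = 1L, sagittal = 2L)
  if (index < 1L || index > d[ax])
    ds_domain_error("slice index out of range")
  keep <- setdiff(1:3, ax)
  v <- switch(plane,
    axial = grid$values[, , index],
    coronal = grid$values[index, , ],
    sagittal = grid$values[, index, ])
  dose_grid(v, spacing = grid$spacing[keep], origin = grid$origin[keep])
}
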