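#' Dose-volume histogram objects
#'
#' A `dvh` stores the binned dose--volume data of one anatomical structure,
#' either in cumulative form (fraction of the structure volume receiving at
#' least each dose) or in differential form (fraction of volume whose dose
#' falls in each bin, mass placed at the bin's left edge). Volumes are
#' unitless fractions; doses are in Gy.
#'
#' Invariants enforced at construction: at least two strictly increasing,
#' non-negative dose bins; cumulative volumes non-increasing within `[0, 1]`;
#' differential volumes non-negative.
#'
#' @param dose numeric vector of dose values in Gy, strictly increasing,
#'   `>= 0`, length `>= 2`.
#' @param volume numeric vector of volume fractions, same length as `dose`.
#' @param kind `"cumulative"` or `"differential"`.
#' @param structure text label for the structure (e.g. `"PTV"`, `"lung"`).
#' @return An object of class `dvh`: a list with elements `structure`,
#'   `kind`, `dose`, `volume`.
#' @examples
#' d <- dvh(c(10, 20), c(0.5, 0.5), kind = "differential", structure = "PTV")
#' mean_dose(d)
#' @export
dvh <- function(dose, volume, kind = c("cumulative", "differential"),
                structure = "structure") {
  kind <- match.arg(kind)
  dose <- as.numeric(dose)
  volume <- as.numeric(volume)
  if (length(dose) < 2L)
    ds_validation_error("a DVH needs at least 2 dose bins")
  if (length(volume) != length(dose))
    ds_validation_error("'dose' and 'volume' must have the same length")
  if (anyNA(dose) || anyNA(volume))
    ds_validation_error("DVH data must not contain NA")
  if (dose[1L] < 0)
    ds_validation_error("dose bins must be >= 0")
  if (any(diff(dose) <= 0))
    ds_validation_error("dose bins must be strictly increasing")
  if (kind == "cumulative") {
    if (any(diff(volume) > 1e-12))
      ds_validation_error("cumulative DVH volume must be non-increasing")
    if (volume[1L] > 1 + 1e-12 || any(volume < -1e-12))
      ds_validation_error("cumulative DVH volume must lie in [0, 1]")
    volume <- pmin(pmax(volume, 0), 1)
    volume <- rev(cummax(rev(volume)))  # kill sub-tolerance wiggles
  } else {
    if (any(volume < -1e-12))
      ds_validation_error("differential DVH volume must be >= 0")
    volume <- pmax(volume, 0)
  }
  structure(
    list(structure = as.character(structure)[1L], kind = kind,
         dose = dose, volume = volume),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s (%s), %d bins, dose %.3g-%.3g Gy\n",
              x$structure, x$kind, length(x$dose),
              min(x$dose), max(x$dose)))
  if (x$kind == "cumulative")
    cat(sprintf("  total volume fraction %.4g\n", x$volume[1L]))
  else
    cat(sprintf("  total volume fraction %.4g\n", sum(x$volume)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ...) {
  cx <- as_cumulative(x)
  graphics::plot(cx$dose, 100 * cx$volume, type = "l",
                 xlab = "Dose (Gy)", ylab = "Volume (%)",
                 main = cx$structure, ...)
  invisible(x)
}

#' Convert between cumulative and differential DVH form
#'
#' `as_differential()` turns a cumulative DVH into differential form: the
#' volume of bin *i* is the decrement of cumulative volume between bins *i*
#' and *i + 1* (any residual cumulative volume at the last bin is kept
#' there), placed at the bin's left edge. `as_cumulative()` is its inverse
#' (reverse cumulative sum). Both are the identity on input that is already
#' in the requested form, and round-trip exactly.
#'
#' @param x a [dvh].
#' @return A [dvh] of the requested kind on the same dose bins.
#' @export
as_differential <- function(x) {
  stopifnot(inherits(x, "dvh"))
  if (x$kind == "differential") return(x)
  n <- length(x$volume)
  v <- c(-diff(x$volume), x$volume[n])
  dvh(x$dose, v, kind = "differential", structure = x$structure)
}

#' @rdname as_differential
#' @export
as_cumulative <- function(x) {
  stopifnot(inherits(x, "dvh"))
  if (x$kind == "cumulative") return(x)
  v <- rev(cumsum(rev(x$volume)))
  if (v[1L] > 1 + 1e-9)
    ds_validation_error("differential DVH volume sums to more than 1")
  dvh(x$dose, pmin(v, 1), kind = "cumulative", structure = x$structure)
}

#' DVH dose and volume queries
#'
#' `dose_at_volume()` returns the smallest dose D such that the fraction of
#' the structure receiving at least D equals `q` (the familiar Dq% index:
#' `dose_at_volume(x, 0.95)` is D95%). `volume_at_dose()` returns the
#' fraction of volume receiving at least dose `d` (the Vd index). Both
#' interpolate linearly between cumulative bins; queries beyond the binned
#' range clamp (`q` above the total fraction returns the lowest bin,
#' `d` above the highest bin returns 0).
#'
#' @param x a [dvh].
#' @param q volume fraction in (0, 1].
#' @param d dose in Gy, `>= 0`.
#' @return A dose in Gy (`dose_at_volume`) or a volume fraction
#'   (`volume_at_dose`).
#' @examples
#' x <- dvh(c(0, 60), c(1, 0), kind = "cumulative")
#' dose_at_volume(x, 0.5)   # 30 Gy
#' volume_at_dose(x, 57)    # 0.05
#' @export
dose_at_volume <- function(x, q) {
  stopifnot(inherits(x, "dvh"))
  stopifnot_scalar_number(q, "q")
  if (q <= 0 || q > 1)
    ds_domain_error("'q' must lie in (0, 1]")
  cx <- as_cumulative(x)
  v <- cx$volume; dd <- cx$dose
  if (q >= v[1L]) return(dd[1L])
  if (q <= v[length(v)]) return(dd[length(dd)])
  # v is non-increasing; find the bracketing segment and interpolate
  i <- max(which(v >= q))
  if (v[i] == v[i + 1L]) return(dd[i + 1L])
  dd[i] + (dd[i + 1L] - dd[i]) * (v[i] - q) / (v[i] - v[i + 1L])
}

#' @rdname dose_at_volume
#' @export
volume_at_dose <- function(x, d) {
  stopifnot(inherits(x, "dvh"))
  stopifnot_scalar_number(d, "d")
  if (d < 0)
    ds_domain_error("'d' must be >= 0")
  cx <- as_cumulative(x)
  v <- cx$volume; dd <- cx$dose
  if (d <= dd[1L]) return(v[1L])
  if (d > dd[length(dd)]) return(0)
  stats::approx(dd, v, xout = d, method = "linear", ties = "ordered")$y
}

#' Mean dose of a DVH
#'
#' The volume-weighted mean dose, computed on the differential form as
#' the sum of bin volume times bin dose. Invariant under the
#' cumulative/differential representation.
#'
#' @param x a [dvh].
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  dx <- as_differential(x)
  tot <- sum(dx$volume)
  if (tot <= 0) return(0)
  sum(dx$volume * dx$dose) / tot
}

#' Rescale all doses of a DVH
#'
#' Multiplies every dose bin by `k`, leaving volumes unchanged. This is how
#' a monitor-unit transfer acts on a DVH (dose is linear in MU for fixed
#' geometry): all dose-type indices (Dq%, Dmean, EUD) scale by exactly `k`.
#'
#' @param x a [dvh].
#' @param k positive scale factor.
#' @return A [dvh] with scaled dose bins.
#' @export
scale_dose <- function(x, k) {
  stopifnot(inherits(x, "dvh"))
  stopifnot_scalar_number(k, "k", positive = TRUE)
  out <- x
  out$dose <- x$dose * k
  out
}

#' Standard DVH indices of a structure
#'
#' Computes the index set the QA workflow tracks: D98% (dose near minimum),
#' D2% (dose near maximum), Dmean, D95%, and -- when a prescription dose is
#' given -- V95% (fraction of volume receiving at least 95% of the
#' prescription).
#'
#' @param x a [dvh].
#' @param dpr prescription dose in Gy, used for V95%; `NULL` to skip.
#' @return Named numeric vector with elements `D98`, `D2`, `Dmean`, `D95`
#'   (Gy) and, if `dpr` is given, `V95` (volume fraction).
#' @export
dvh_metrics <- function(x, dpr = NULL) {
  out <- c(
    D98 = dose_at_volume(x, 0.98),
    D2 = dose_at_volume(x, 0.02),
    Dmean = mean_dose(x),
    D95 = dose_at_volume(x, 0.95)
  )
  if (!is.null(dpr)) {
    stopifnot_scalar_number(dpr, "dpr", positive = TRUE)
    out <- c(out, V95 = volume_at_dose(x, 0.95 * dpr))
  }
  out
}
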