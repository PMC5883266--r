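# Independent oracles and fixture builders used across the suite.

# Exhaustive-enumeration oracle for the two-sided Wilcoxon signed-rank p:
# all 2^n sign assignments over the midranks of |d| (zeros dropped).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force gamma oracle: exhaustive search over a finely subsampled
# candidate lattice (step = spacing / subsample) within the search cap,
# with the evaluated dose computed by direct bilinear interpolation.
# 2D grids with uniform spacing only; independent of the package's
# upsampling-matrix implementation.
oracle_gamma_2d <- function(ref_values, eval_values, spacing, dd_percent,
                            dta_mm, norm_dose, search_cap_mm = 3 * dta_mm,
                            subsample = 10L) {
  nr <- nrow(ref_values); nc <- ncol(ref_values)
  dd_abs <- dd_percent / 100 * norm_dose
  fs <- spacing / subsample
  hw <- floor(search_cap_mm / fs)
  offs <- (-hw:hw) * fs
  grid_off <- expand.grid(ox = offs, oy = offs)
  bilinear <- function(x_mm, y_mm) {
    # physical mm -> fractional indices (origin at first voxel centre)
    fx <- x_mm / spacing + 1
    fy <- y_mm / spacing + 1
    i0 <- pmax(pmin(floor(fx), nr - 1), 1)
    j0 <- pmax(pmin(floor(fy), nc - 1), 1)
    tx <- fx - i0
    ty <- fy - j0
    v00 <- eval_values[cbind(i0, j0)]
    v10 <- eval_values[cbind(i0 + 1, j0)]
    v01 <- eval_values[cbind(i0, j0 + 1)]
    v11 <- eval_values[cbind(i0 + 1, j0 + 1)]
    v00 * (1 - tx) * (1 - ty) + v10 * tx * (1 - ty) +
      v01 * (1 - tx) * ty + v11 * tx * ty
  }
  gam <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x0 <- (i - 1) * spacing
      y0 <- (j - 1) * spacing
      xs <- x0 + grid_off$ox
      ys <- y0 + grid_off$oy
      inside <- xs >= 0 & xs <= (nr - 1) * spacing &
        ys >= 0 & ys <= (nc - 1) * spacing
      de <- bilinear(xs[inside], ys[inside])
      dist2 <- grid_off$ox[inside]^2 + grid_off$oy[inside]^2
      gam[i, j] <- sqrt(min((de - ref_values[i, j])^2 / dd_abs^2 +
                              dist2 / dta_mm^2))
    }
  }
  gam
}

# random smooth-ish dose field for gamma property tests
random_dose_field <- function(n = 16, base = 50, seed = 1) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n)
  f <- outer(sin(2 * pi * x * runif(1, 0.5, 1.5)) + 1.2,
             cos(2 * pi * x * runif(1, 0.5, 1.5)) + 1.2)
  f <- f / max(f) * base
  f + matrix(runif(n * n, 0, 0.02 * base), n, n)
}

# random clinically realistic target-coverage DVH: narrow dose spread
# (0.85-1.10 of the level), fine bins. The D98 <= EUD <= D2 bracket is a
# statement about such DVHs -- with a long cold tail the a = -10
# generalized mean drops toward the minimum dose and the bracket fails.
random_clinical_dvh <- function(seed) {
  set.seed(seed)
  d50 <- runif(1, 20, 70)
  n <- sample(20:60, 1)
  dose <- d50 * sort(runif(n, 0.85, 1.10))
  w <- runif(n)^2
  dvh(dose, w / sum(w), kind = "differential",
      structure = sprintf("clin%d", seed))
}

# random valid differential DVH
random_dvh <- function(seed, n_bins = NULL, min_dose = 1) {
  set.seed(seed)
  if (is.null(n_bins)) n_bins <- sample(3:30, 1)
  dose <- sort(min_dose + cumsum(runif(n_bins, 0.1, 4)))
  v <- runif(n_bins)
  v <- v / sum(v)
  dvh(dose, v, kind = "differential", structure = sprintf("rand%d", seed))
}
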