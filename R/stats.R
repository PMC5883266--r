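#' Paired dosimetric sample
#'
#' A pair of aligned measurement vectors (e.g. per-beam monitor units from
#' the reference and the tested algorithm). Dosimetric data recalculated on
#' the same CT are statistically paired, which is what makes the
#' signed-rank test applicable at very small sample sizes.
#'
#' @param reference numeric vector from the reference algorithm.
#' @param test numeric vector from the tested algorithm, same length,
#'   length `>= 2`.
#' @param unit text label for the unit (e.g. `"MU"`, `"Gy"`).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(reference, test, unit = "") {
  reference <- as.numeric(reference)
  test <- as.numeric(test)
  if (length(reference) != length(test))
    ds_validation_error("'reference' and 'test' must have the same length")
  if (length(reference) < 2L)
    ds_validation_error("paired samples need at least 2 cases")
  if (anyNA(reference) || anyNA(test))
    ds_validation_error("paired samples must not contain NA")
  structure(list(reference = reference, test = test,
                 unit = as.character(unit)[1L]),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> m = %d%s, mean difference %.4g\n",
              length(x$reference),
              if (nzchar(x$unit)) paste0(" (", x$unit, ")") else "",
              mean(x$test - x$reference)))
  invisible(x)
}

# exact null distribution of the doubled signed-rank statistic for a given
# multiset of doubled midranks (integers); cached because the bootstrap
# evaluates many resamples with recurring rank patterns
.signrank_cache <- new.env(parent = emptyenv())

signrank_exact_dist <- function(ranks2) {
  key <- paste(sort(ranks2), collapse = ",")
  hit <- .signrank_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(ranks2)
  dist <- numeric(total + 1L)   # index k+1 holds P(W2 == k)
  dist[1L] <- 1
  for (s in ranks2) {
    shifted <- c(numeric(s), dist[seq_len(total + 1L - s)])
    dist <- (dist + shifted) / 2
  }
  .signrank_cache[[key]] <- dist
  dist
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on the paired differences, with average ranks
#' for tied absolute differences and zero differences discarded before
#' ranking. The exact p-value is computed from the full null distribution
#' of the statistic (a convolution over the doubled midranks, equivalent to
#' enumerating all 2^n sign assignments) for n up to 25; beyond that a
#' normal approximation with tie and continuity correction is used.
#' The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param sample a [paired_sample].
#' @param mode `"auto"` (exact up to n = 25), `"exact"` or `"approx"`.
#' @return List with `statistic` (sum of positive-difference ranks W),
#'   `p_value`, `n_used` (non-zero differences) and `mode` used.
#' @examples
#' s <- paired_sample(c(0, 0, 0, 0, 0), c(1, 2, 3, 4, 5))
#' wilcoxon_signed_rank(s)$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(sample, mode = c("auto", "exact", "approx")) {
  stopifnot(inherits(sample, "paired_sample"))
  mode <- match.arg(mode)
  d <- sample$test - sample$reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    ds_domain_error("all paired differences are zero; no test possible")
  r <- rank(abs(d))                     # average ranks for ties
  w <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 25L) "exact" else "approx"
  if (mode == "exact") {
    ranks2 <- as.integer(round(2 * r))
    dist <- signrank_exact_dist(ranks2)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n_used = n, mode = mode)
}

#' Spearman rank correlation of a paired sample
#'
#' Rank correlation with average-rank tie handling (Pearson correlation of
#' the midranks). Strong positive correlation is expected between paired
#' dosimetric series that differ only by the calculation algorithm.
#'
#' @param sample a [paired_sample] with at least 3 cases.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  x <- sample$reference; y <- sample$test
  if (length(x) < 3L)
    ds_domain_error("Spearman correlation needs at least 3 cases")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    ds_domain_error("Spearman correlation is undefined for a constant sequence")
  stats::cor(rank(x), rank(y))
}

#' Bootstrap p-value curve against sample size
#'
#' Estimates, by resampling, the smallest number of paired cases at which a
#' dosimetric difference becomes statistically detectable. For each sample
#' size n from `n_min` up to the number of cases m, `B` resamples of size n
#' are drawn with replacement from the pairs; the two-sided signed-rank
#' p-value is computed on each (a resample whose differences are all zero
#' contributes p = 1), and the per-n mean (optionally median) p is
#' recorded. The curve is a deterministic function of `(sample, B, seed)`.
#'
#' @param sample a [paired_sample].
#' @param B number of resamples per sample size (default 1000).
#' @param n_min smallest resample size (default 2).
#' @param seed integer seed for the resampling generator (required for
#'   reproducibility).
#' @param alpha significance level carried on the curve (default 0.05).
#' @param aggregate `"mean"` (default) or `"median"` p-value per n.
#' @return An object of class `bootstrap_curve`: list with `n_values`,
#'   `mean_p`, `B`, `seed`, `alpha`, `aggregate`.
#' @export
bootstrap_pcurve <- function(sample, B = 1000L, n_min = 2L, seed,
                             alpha = 0.05, aggregate = c("mean", "median")) {
  stopifnot(inherits(sample, "paired_sample"))
  aggregate <- match.arg(aggregate)
  B <- as.integer(B)
  if (B <= 0L) ds_domain_error("'B' must be a positive integer")
  m <- length(sample$reference)
  n_min <- as.integer(n_min)
  if (n_min < 2L || n_min > m)
    ds_domain_error("'n_min' must lie in [2, m]")
  if (missing(seed)) ds_domain_error("'seed' is required")
  seed <- as.integer(seed)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ref <- sample$reference; tst <- sample$test
  n_values <- n_min:m
  agg_fun <- if (aggregate == "mean") mean else stats::median
  mean_p <- vapply(n_values, function(n) {
    ps <- vapply(seq_len(B), function(b) {
      idx <- sample.int(m, n, replace = TRUE)
      d <- tst[idx] - ref[idx]
      if (all(d == 0)) return(1)
      wilcoxon_signed_rank(paired_sample(ref[idx], tst[idx]))$p_value
    }, numeric(1))
    agg_fun(ps)
  }, numeric(1))

  structure(
    list(n_values = n_values, mean_p = mean_p, B = B, seed = seed,
         alpha = alpha, aggregate = aggregate),
    class = "bootstrap_curve"
  )
}

#' @export
print.bootstrap_curve <- function(x, ...) {
  nmin <- minimal_significant_n(x)
  cat(sprintf("<bootstrap_curve> n = %d..%d, B = %d, seed = %d\n",
              min(x$n_values), max(x$n_values), x$B, x$seed))
  cat(sprintf("  minimal n with %s p < %g: %s\n", x$aggregate, x$alpha,
              if (is.na(nmin)) "never crossed" else nmin))
  invisible(x)
}

#' @export
plot.bootstrap_curve <- function(x, ...) {
  graphics::plot(x$n_values, x$mean_p, type = "b", pch = 16,
                 xlab = "sample size n", ylab = sprintf("%s p-value", x$aggregate),
                 ylim = c(0, max(x$mean_p, 0.06)), ...)
  graphics::abline(h = c(0.05, 0.025), lty = 2, col = c("red", "blue"))
  invisible(x)
}

#' @export
as.data.frame.bootstrap_curve <- function(x, ...) {
  data.frame(n = x$n_values, mean_p = x$mean_p)
}

#' Minimal sample size crossing the significance level
#'
#' The smallest n whose aggregated bootstrap p-value falls below the
#' curve's significance level; `NA` if the level is never crossed.
#'
#' @param curve a [bootstrap_curve].
#' @param alpha significance level; defaults to the one on the curve.
#' @return Integer n, or `NA_integer_`.
#' @export
minimal_significant_n <- function(curve, alpha = curve$alpha) {
  stopifnot(inherits(curve, "bootstrap_curve"))
  i <- which(curve$mean_p < alpha)
  if (length(i) == 0L) return(NA_integer_)
  as.integer(curve$n_values[min(i)])
}
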