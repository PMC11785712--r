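#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test. The score is
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}; its variance uses the
#' standard tie correction
#' \eqn{\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)]/18}
#' over tie groups of size \eqn{t_g}. The p-value comes from the normal
#' approximation with a +/-1 continuity correction, which is accurate for
#' the series lengths (~25 years) this package targets; the exact null
#' distribution is not implemented.
#'
#' @param x Numeric series (ordered in time, equally spaced or not; only
#'   the order matters for S).
#' @param alpha Confidence level used for the Theil-Sen slope interval
#'   attached to the result.
#' @return An object of class `trend_result`: a list with `S`, `varS`, `Z`,
#'   `p_value` (two-sided), `n`, and the Theil-Sen `sen_slope`,
#'   `sen_intercept` and `slope_ci` computed against time 1..n.
#' @seealso [theil_sen()] for the slope estimator on arbitrary time axes.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10))
#' @export
mann_kendall <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite and complete")
  n <- length(x)
  if (n < 4L) stop("insufficient data: Mann-Kendall needs n >= 4")

  d <- outer(x, x, "-")            # d[j, i] = x[j] - x[i]
  S <- sum(sign(d[lower.tri(d)]))  # j > i pairs

  ties <- table(x)
  t_g <- as.numeric(ties[ties > 1L])
  varS <- (n * (n - 1) * (2 * n + 5) - sum(t_g * (t_g - 1) * (2 * t_g + 5))) / 18

  if (varS <= 0) {                 # all values identical
    Z <- 0
    p <- 1
  } else {
    Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
    p <- 2 * stats::pnorm(-abs(Z))
  }

  ts <- theil_sen(x, seq_len(n), alpha = alpha, .varS = varS)
  structure(
    list(S = S, varS = varS, Z = Z, p_value = p, n = n,
         sen_slope = ts$slope, sen_intercept = ts$intercept,
         slope_ci = ts$ci, conf_level = 1 - alpha),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Mann-Kendall / Theil-Sen trend\n")
  cat(sprintf("  n = %d, S = %d, var(S) = %.2f, Z = %.3f, p = %.4g\n",
              x$n, x$S, x$varS, x$Z, x$p_value))
  cat(sprintf("  Sen slope = %.5g  [%.5g, %.5g] (%.0f%% CI), intercept = %.5g\n",
              x$sen_slope, x$slope_ci[1], x$slope_ci[2],
              100 * x$conf_level, x$sen_intercept))
  invisible(x)
}

#' Theil-Sen slope estimator
#'
#' Median of all pairwise slopes \eqn{(x_j - x_i)/(t_j - t_i)} over pairs
#' with distinct times; pairs sharing a time value are excluded. The
#' intercept is `median(x - slope * t)`. The confidence interval is the
#' classical rank-based one: with \eqn{C = z_{1-\alpha/2}\sqrt{var(S)}}
#' the bounds are the slopes of rank \eqn{(N'-C)/2} and \eqn{(N'+C)/2 + 1}
#' among the \eqn{N'} ordered pairwise slopes.
#'
#' @param x Numeric values.
#' @param t Time axis (same length as `x`).
#' @param alpha One minus the confidence level for the slope CI.
#' @param .varS Internal: precomputed Mann-Kendall variance (avoids
#'   recomputation when called from [mann_kendall()]).
#' @return List with `slope`, `intercept`, `ci` (length-2), `n_slopes`.
#' @examples
#' theil_sen(c(1, 3, 5, 7, 100), 1:5)$slope  # robust to the outlier
#' @export
theil_sen <- function(x, t, alpha = 0.05, .varS = NULL) {
  x <- as.numeric(x); t <- as.numeric(t)
  if (length(x) != length(t)) stop("x and t must have equal length")
  n <- length(x)
  if (n < 2L) stop("insufficient data")

  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # row j > col i
  dt <- t[ij[, 1L]] - t[ij[, 2L]]
  keep <- dt != 0
  slopes <- (x[ij[, 1L]] - x[ij[, 2L]])[keep] / dt[keep]
  if (length(slopes) == 0L) stop("no pairs with distinct times")

  slope <- stats::median(slopes)
  intercept <- stats::median(x - slope * t)

  if (is.null(.varS)) {
    ties <- table(x)
    t_g <- as.numeric(ties[ties > 1L])
    .varS <- (n * (n - 1) * (2 * n + 5) - sum(t_g * (t_g - 1) * (2 * t_g + 5))) / 18
  }
  k <- sort(slopes)
  N <- length(k)
  C <- stats::qnorm(1 - alpha / 2) * sqrt(max(.varS, 0))
  lo_i <- max(1L, floor((N - C) / 2))
  hi_i <- min(N, ceiling((N + C) / 2 + 1))
  ci <- c(k[lo_i], k[hi_i])
  ci <- c(min(ci[1], slope), max(ci[2], slope))  # CI always brackets the point estimate

  list(slope = slope, intercept = intercept, ci = ci, n_slopes = N)
}

#' Partial correlation with one control variable
#'
#' First-order partial correlation
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' with the p-value from \eqn{t = r\sqrt{(n-3)/(1-r^2)}} on \eqn{n-3}
#' degrees of freedom. Used throughout to relate vintage component scores
#' to bioclimatic indices while controlling for the common time trend
#' (control = calendar year).
#'
#' @param x,y Numeric vectors of equal length.
#' @param control Control variable, same length.
#' @return List with `r_partial`, `p_value`, `n`, `df`.
#' @examples
#' yr <- 1:25
#' partial_correlation(yr + rnorm(25), yr + rnorm(25), control = yr)
#' @export
partial_correlation <- function(x, y, control) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(control)
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y and control must have equal length")
  if (n < 4L) stop("insufficient data: partial correlation needs n >= 4")
  if (anyNA(c(x, y, z))) stop("missing values not allowed")

  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate control: a variable is collinear with the control")

  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- max(-1, min(1, r))
  df <- n - 3L
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  list(r_partial = r, p_value = p, n = n, df = df)
}

# Mid-ranks of the pooled sample plus the tie-group sizes; shared by the
# Kruskal-Wallis and Conover-Iman routines.
.pooled_ranks <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)  # mid-ranks
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  ties <- table(pooled)
  list(r = r, idx = idx, sizes = sizes, N = length(pooled),
       tie_sizes = as.numeric(ties[ties > 1L]))
}

#' Kruskal-Wallis rank test
#'
#' Mid-rank H statistic with the tie correction
#' \eqn{H' = H / (1 - \sum(t^3 - t)/(N^3 - N))}; p-value from the
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return List with `H` (tie-corrected), `p_value`, `df`, `n`,
#'   `rank_means`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("every group must be nonempty")
  pr <- .pooled_ranks(groups)
  N <- pr$N
  if (N < 3L) stop("insufficient data: total n >= 3 required")
  k <- length(groups)

  R <- tapply(pr$r, pr$idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / pr$sizes) - 3 * (N + 1)
  tie_corr <- 1 - sum(pr$tie_sizes^3 - pr$tie_sizes) / (N^3 - N)
  if (tie_corr <= 0) {          # every observation identical
    H <- 0
    p <- 1
  } else {
    H <- H / tie_corr
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  list(H = H, p_value = p, df = k - 1L, n = N,
       rank_means = as.numeric(R / pr$sizes))
}

#' Conover-Iman post-hoc pairwise comparisons
#'
#' Follow-up to [kruskal_wallis()] identifying which groups differ: the
#' pairwise statistic on rank means is
#' \deqn{t_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{S^2 \frac{N-1-H}{N-k} (1/n_i + 1/n_j)}}}
#' with the pooled rank variance \eqn{S^2 = (\sum r^2 - N(N+1)^2/4)/(N-1)}
#' computed from mid-ranks (which absorbs ties), compared to a t
#' distribution on N-k degrees of freedom. P-values are reported raw and
#' Holm-adjusted.
#'
#' @param groups A list of numeric vectors; names are used as group labels.
#' @param alpha Significance level for the `significant` flags (applied to
#'   adjusted p-values).
#' @param p_adjust Multiple-comparison adjustment method (see
#'   [stats::p.adjust()]); default `"holm"`.
#' @return A data.frame with one row per unordered pair: `group1`,
#'   `group2`, `t`, `p_raw`, `p_adj`, `significant`.
#' @export
conover_iman <- function(groups, alpha = 0.05, p_adjust = "holm") {
  kw <- kruskal_wallis(groups)
  pr <- .pooled_ranks(groups)
  N <- pr$N
  k <- length(groups)
  if (N <= k) stop("need N > k observations for the pooled rank variance")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))

  S2 <- (sum(pr$r^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- kw$rank_means
  scale_fac <- S2 * (N - 1 - kw$H) / (N - k)
  scale_fac <- max(scale_fac, 0)

  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = labels[pairs[1, ]],
    group2 = labels[pairs[2, ]],
    t = NA_real_, p_raw = NA_real_,
    stringsAsFactors = FALSE
  )
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt(scale_fac * (1 / pr$sizes[i] + 1 / pr$sizes[j]))
    tval <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    out$t[c_i] <- tval
    out$p_raw[c_i] <- 2 * stats::pt(-abs(tval), df = N - k)
  }
  out$p_adj <- stats::p.adjust(out$p_raw, method = p_adjust)
  out$significant <- out$p_adj < alpha
  out
}

#' Critical Pearson correlation threshold
#'
#' Smallest |r| significant at level `alpha` for a sample of size `n`:
#' \eqn{r^* = t^* / \sqrt{n - 2 + t^{*2}}} where \eqn{t^*} is the
#' two-sided critical t value on n-2 degrees of freedom. At n = 25 and
#' alpha = 0.05 this is 0.396, the +/-0.40 masking threshold used for
#' 25-year correlation maps.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return The critical correlation magnitude in (0, 1).
#' @examples
#' critical_r(25)        # ~0.396
#' @export
critical_r <- function(n, alpha = 0.05, two_sided = TRUE) {
  if (n < 3) stop("n must be >= 3")
  df <- n - 2
  tail <- if (two_sided) alpha / 2 else alpha
  tstar <- stats::qt(1 - tail, df)
  tstar / sqrt(df + tstar^2)
}
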