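# Tercile-composite monthly anomaly analysis: per-calendar-month linear
# detrending, tercile classification of an annual index, composite
# residual anomalies over the extreme-tercile years, and bootstrap
# 5th/95th-percentile significance envelopes.

#' Per-calendar-month linear detrending
#'
#' For each calendar month independently, an ordinary-least-squares line
#' in year is fitted and removed; the residual (original minus fitted
#' trend) is returned. Residuals of every month average to zero by
#' construction, so composites over year subsets are anomalies relative
#' to the month's trend line.
#'
#' @param monthly data.frame with columns `year`, `month`, `value`.
#' @param min_years Months observed in fewer years are excluded with a
#'   warning (default 4).
#' @return The input with added columns `fitted` and `residual`, months
#'   with insufficient coverage dropped.
#' @export
detrend_monthly <- function(monthly, min_years = 4L) {
  stopifnot(all(c("year", "month", "value") %in% names(monthly)))
  out <- monthly
  out$fitted <- NA_real_
  out$residual <- NA_real_
  drop_m <- integer(0)
  for (m in sort(unique(out$month))) {
    sel <- which(out$month == m)
    if (length(sel) < min_years) { drop_m <- c(drop_m, m); next }
    fit <- stats::lm.fit(cbind(1, out$year[sel]), out$value[sel])
    out$fitted[sel] <- out$value[sel] - fit$residuals
    out$residual[sel] <- fit$residuals
  }
  if (length(drop_m)) {
    warning("months excluded (fewer than ", min_years, " years): ",
            paste(drop_m, collapse = ", "))
    out <- out[!out$month %in% drop_m, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Tercile classification of an annual index
#'
#' After optional linear detrending of the index itself, the
#' `m = floor(n/3)` smallest values form the low set and the `m` largest
#' the high set; the remainder are mid. Ties straddling a tercile
#' boundary are broken by year order — the earlier year enters the
#' extreme set.
#'
#' @param years Integer vector of years.
#' @param values Annual index values, same length.
#' @param detrend Detrend the index before classifying (default TRUE).
#' @return Object of class `terciled_series`: data.frame `year`, `value`,
#'   `detrended`, `tercile` (factor low/mid/high) with attributes
#'   `low_years`, `high_years`, `m`.
#' @export
classify_terciles <- function(years, values, detrend = TRUE) {
  n <- length(years)
  if (length(values) != n) stop("years and values must have equal length")
  if (n < 3L) stop("insufficient data: tercile classification needs n >= 3")
  dt <- if (detrend && n >= 4L) .detrend_vec(values, years) else values
  m <- n %/% 3L

  ord_low <- order(dt, years)                 # ties: earlier year first
  ord_high <- order(-dt, years)
  low_years <- years[ord_low[seq_len(m)]]
  high_years <- years[ord_high[seq_len(m)]]

  terc <- rep("mid", n)
  terc[years %in% low_years] <- "low"
  terc[years %in% high_years] <- "high"
  out <- data.frame(year = years, value = values, detrended = dt,
                    tercile = factor(terc, levels = c("low", "mid", "high")))
  attr(out, "low_years") <- sort(low_years)
  attr(out, "high_years") <- sort(high_years)
  attr(out, "m") <- m
  class(out) <- c("terciled_series", "data.frame")
  out
}

#' Composite mean anomaly over a year set
#'
#' Arithmetic mean of the detrended residuals over the given years, per
#' calendar month.
#'
#' @param residuals Output of [detrend_monthly()] (needs `year`, `month`,
#'   `residual`).
#' @param year_set Years to composite over.
#' @return data.frame `month`, `composite`.
#' @export
composite_anomalies <- function(residuals, year_set) {
  stopifnot(all(c("year", "month", "residual") %in% names(residuals)))
  sel <- residuals$year %in% year_set
  if (!any(sel)) stop("no residuals in the given year set")
  r <- residuals[sel, , drop = FALSE]
  months <- sort(unique(residuals$month))
  data.frame(
    month = months,
    composite = vapply(months, function(m) mean(r$residual[r$month == m]),
                       numeric(1))
  )
}

#' Bootstrap significance envelope for composites
#'
#' Draws `n_boot` random samples of `m` years (with replacement by
#' default; `replace = FALSE` gives the subsampling variant), averages
#' the residuals of each draw per calendar month, and returns the stated
#' percentiles of the replicate means. One set of year draws per
#' replicate is reused across all months, preserving cross-month
#' dependence.
#'
#' @param residuals Output of [detrend_monthly()].
#' @param m Sample size per replicate (the tercile size).
#' @param n_boot Number of replicates (default 10000).
#' @param percentiles Lower/upper percentiles (default 5 and 95).
#' @param seed Integer seed (reproducible envelopes).
#' @param replace Sample years with replacement?
#' @return data.frame `month`, `lower`, `upper`.
#' @export
bootstrap_envelope <- function(residuals, m, n_boot = 10000L,
                               percentiles = c(5, 95), seed = 1L,
                               replace = TRUE) {
  stopifnot(all(c("year", "month", "residual") %in% names(residuals)))
  if (n_boot < 100L) stop("n_boot must be >= 100")
  years <- sort(unique(residuals$year))
  ny <- length(years)
  if (!replace && m > ny)
    stop("m exceeds the number of years in without-replacement mode")
  months <- sort(unique(residuals$month))
  # residual matrix month x year (months guaranteed complete by detrend)
  R <- matrix(NA_real_, length(months), ny,
              dimnames = list(months, years))
  idx <- cbind(match(residuals$month, months), match(residuals$year, years))
  R[idx] <- residuals$residual

  set.seed(as.integer(seed))
  if (replace) {
    draws <- matrix(sample.int(ny, n_boot * m, replace = TRUE), nrow = m)
  } else {
    draws <- vapply(seq_len(n_boot), function(i) sample.int(ny, m),
                    integer(m))
  }
  # replicate means: for each month row, average R[month, draws] per column
  boot_means <- vapply(seq_len(nrow(R)), function(mi) {
    v <- R[mi, ]
    colMeans(matrix(v[draws], nrow = m), na.rm = TRUE)
  }, numeric(n_boot))                         # n_boot x n_months

  qs <- apply(boot_means, 2, stats::quantile,
              probs = percentiles / 100, na.rm = TRUE, names = FALSE)
  data.frame(month = months, lower = qs[1, ], upper = qs[2, ])
}

#' Tercile-composite report for one variable
#'
#' Orchestrates the full procedure on a monthly multi-year series and an
#' annual index: per-month detrending, tercile classification of the
#' index, high- and low-composite anomalies, a shared bootstrap envelope
#' (both extreme sets have the same size m), and significance flags
#' (composite outside the envelope).
#'
#' @param monthly data.frame `year`, `month`, `value` (the variable).
#' @param index data.frame `year`, `value` (the annual index) or a
#'   [classify_terciles()] result.
#' @param n_boot,percentiles,seed,replace Passed to
#'   [bootstrap_envelope()].
#' @param detrend_index Detrend the index before tercile classification?
#' @return Object of class `composite_result`: data.frame `month`,
#'   `category` (high/low), `composite`, `lower`, `upper`, `significant`;
#'   attributes `terciles`, `n_boot`, `seed`.
#' @export
composite_report <- function(monthly, index, n_boot = 10000L,
                             percentiles = c(5, 95), seed = 1L,
                             replace = TRUE, detrend_index = TRUE) {
  res <- detrend_monthly(monthly)
  terc <- if (inherits(index, "terciled_series")) index
          else classify_terciles(index$year, index$value,
                                 detrend = detrend_index)
  m <- attr(terc, "m")
  env <- bootstrap_envelope(res, m = m, n_boot = n_boot,
                            percentiles = percentiles, seed = seed,
                            replace = replace)
  one <- function(cat_years, label) {
    comp <- composite_anomalies(res, cat_years)
    df <- merge(comp, env, by = "month")
    df$category <- label
    df$significant <- df$composite < df$lower | df$composite > df$upper
    df
  }
  out <- rbind(one(attr(terc, "high_years"), "high"),
               one(attr(terc, "low_years"), "low"))
  out <- out[order(out$category, out$month),
             c("month", "category", "composite", "lower", "upper",
               "significant")]
  rownames(out) <- NULL
  attr(out, "terciles") <- terc
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("composite_result", "data.frame")
  out
}
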