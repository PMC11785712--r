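# Vintage-table generator: each annual wine variable responds linearly to
# standardized May/June/July maximum-temperature anomalies and to a
# standardized growing-season water balance, plus Gaussian noise. The
# linear-additive structure makes partial-correlation and tercile-composite
# recovery analytically predictable, and the ground-truth coefficients are
# returned with the table for parameter-recovery tests.

.vintage_vars <- c("pvad", "ph", "tta", "wb100", "veraison_doy",
                   "harvest_doy", "production", "yield")

#' Vintage response configuration
#'
#' Slopes map the four standardized drivers (May, June, July TX anomaly;
#' growing-season water balance) to each vintage variable. Default signs
#' encode the causal structure a hot, dry ripening season imposes:
#' probable alcohol (PVAD) and pH rise with heat, total tartaric acidity
#' (TTA) and the veraison/harvest dates fall, and 100-berry weight
#' (WB100) rises with wetness. Production and yield are left uncoupled by
#' default (management-driven in practice).
#'
#' @param baseline Named numeric vector of per-variable baselines
#'   (pvad %vol, ph, tta g/L, wb100 g, veraison/harvest day-of-year,
#'   production, yield).
#' @param slopes Numeric matrix, rows = variables, columns
#'   `c("may","jun","jul","wb")`: response per standard deviation of each
#'   driver.
#' @param noise_sd Named numeric vector of per-variable noise standard
#'   deviations (>= 0).
#' @param rating_heat Coupling of the latent vintage-rating quality to
#'   mean summer heat.
#' @param rating_noise_sd Noise sd of the latent rating variable.
#' @param rating_probs Probabilities of the `good`, `very good`,
#'   `excellent` categories under the null (sum to 1).
#' @return List of class `vintage_response_config`.
#' @export
vintage_response_config <- function(
    baseline = c(pvad = 13.0, ph = 3.55, tta = 6.5, wb100 = 180,
                 veraison_doy = 222, harvest_doy = 274,
                 production = 280, yield = 6500),
    slopes = rbind(
      pvad         = c(may = 0.25, jun = 0.15, jul = 0.20, wb = -0.05),
      ph           = c(0.040, 0.030, 0.030, -0.010),
      tta          = c(-0.30, -0.20, -0.20, 0.10),
      wb100        = c(-2.0, -1.0, -1.0, 6.0),
      veraison_doy = c(-2.5, -2.0, -1.5, 0.5),
      harvest_doy  = c(-2.0, -1.5, -1.5, 1.0),
      production   = c(0, 0, 0, 0),
      yield        = c(0, 0, 0, 0)),
    noise_sd = c(pvad = 0.25, ph = 0.04, tta = 0.30, wb100 = 8,
                 veraison_doy = 3, harvest_doy = 4,
                 production = 25, yield = 400),
    rating_heat = 0.4, rating_noise_sd = 1.0,
    rating_probs = c(good = 0.30, `very good` = 0.42, excellent = 0.28)) {
  colnames(slopes) <- c("may", "jun", "jul", "wb")
  rownames(slopes) <- .vintage_vars
  if (any(noise_sd < 0)) stop("configuration error: noise sd must be >= 0")
  if (!all(.vintage_vars %in% names(baseline)))
    stop("baseline must name all vintage variables")
  if (abs(sum(rating_probs) - 1) > 1e-8)
    stop("rating probabilities must sum to 1")
  structure(list(baseline = baseline[.vintage_vars],
                 slopes = slopes, noise_sd = noise_sd[.vintage_vars],
                 rating_heat = rating_heat,
                 rating_noise_sd = rating_noise_sd,
                 rating_probs = rating_probs),
            class = "vintage_response_config")
}

# Standardized drivers from a daily weather series: May/Jun/Jul monthly
# mean TX anomalies and an April-September water balance (P - Thornthwaite
# PET), each scaled across years. With fewer than 2 distinct values the
# z-score is defined as 0.
.vintage_drivers <- function(weather, latitude = 42.45) {
  monthly <- aggregate_monthly(weather)
  years <- sort(unique(monthly$year))
  years <- years[vapply(years, function(y) sum(monthly$year == y) == 12L,
                        logical(1))]
  zcol <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  pick <- function(m) vapply(years, function(y)
    monthly$tx[monthly$year == y & monthly$month == m], numeric(1))
  wbal <- vapply(years, function(y) {
    my <- monthly[monthly$year == y, ]
    my <- my[order(my$month), ]
    pet <- thornthwaite_pet((my$tx + my$tn) / 2, latitude, y)
    sum(my$pp_total[4:9]) - sum(pet[4:9])
  }, numeric(1))
  data.frame(year = years, may = zcol(pick(5)), jun = zcol(pick(6)),
             jul = zcol(pick(7)), wb = zcol(wbal))
}

#' Generate an annual vintage table from daily weather
#'
#' One row per full calendar year. Each variable is
#' `baseline + slopes %*% drivers + noise`; day-of-year fields are rounded
#' and clamped to [1, 366]. The vintage rating is an ordered category
#' (`good` < `very good` < `excellent`) cut from a latent quality variable
#' coupled to mean summer heat.
#'
#' @param weather Daily weather series spanning at least 3 full years.
#' @param config A [vintage_response_config()].
#' @param seed Integer seed.
#' @return data.frame with `year`, the eight vintage variables and
#'   `rating`; attributes `coefficients` (the ground-truth slope matrix),
#'   `baseline`, `noise_sd` and `drivers` (the standardized driver table)
#'   for recovery tests.
#' @export
generate_wine_table <- function(weather, config = vintage_response_config(),
                                seed = 1L) {
  stopifnot(inherits(config, "vintage_response_config"))
  drivers <- .vintage_drivers(weather)
  n <- nrow(drivers)
  if (n < 3L) stop("insufficient data: weather must span >= 3 full years")
  set.seed(as.integer(seed))

  Z <- as.matrix(drivers[, c("may", "jun", "jul", "wb")])
  out <- data.frame(year = drivers$year)
  for (v in .vintage_vars) {
    eff <- as.numeric(Z %*% config$slopes[v, ])
    out[[v]] <- config$baseline[[v]] + eff +
      stats::rnorm(n, 0, config$noise_sd[[v]])
  }
  for (v in c("veraison_doy", "harvest_doy"))
    out[[v]] <- pmin(366, pmax(1, round(out[[v]])))

  heat <- rowMeans(Z[, c("may", "jun", "jul"), drop = FALSE])
  latent <- config$rating_heat * heat +
    stats::rnorm(n, 0, config$rating_noise_sd)
  lsd <- sqrt(config$rating_heat^2 + config$rating_noise_sd^2)
  lab <- names(config$rating_probs)
  if (lsd > 0) {
    cuts <- stats::qnorm(cumsum(config$rating_probs)[1:2]) * lsd
    rating <- cut(latent, breaks = c(-Inf, cuts[1], cuts[2], Inf),
                  labels = lab, right = TRUE)
  } else {
    rating <- rep(lab[1], n)   # degenerate latent: identical vintages
  }
  out$rating <- factor(as.character(rating), levels = lab, ordered = TRUE)

  attr(out, "coefficients") <- config$slopes
  attr(out, "baseline") <- config$baseline
  attr(out, "noise_sd") <- config$noise_sd
  attr(out, "drivers") <- drivers
  attr(out, "seed") <- as.integer(seed)
  out
}
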