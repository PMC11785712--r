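# Stochastic daily weather generator: sinusoidal seasonal cycles with AR(1)
# Gaussian anomalies for temperature, a two-state Markov chain with
# gamma-distributed amounts for precipitation, and sunshine/cloud/humidity
# derived from the temperature anomaly and wet/dry state. Emulates a
# Mediterranean-continental station climatology (hot dry summers, spring
# and autumn precipitation maxima, ~405 mm/yr) with a configurable
# warming trend.

#' Weather generator configuration
#'
#' Defaults emulate the Logrono-Agoncillo station climatology: annual
#' mean TX about 18.3 degC with a 10.5 degC seasonal half-amplitude,
#' TN 7.8 +/- 7 degC, persistent (AR1 = 0.7) daily anomalies, a 0.4
#' degC/decade warming trend, and Markov-gamma precipitation calibrated
#' so the expected annual total is 405 mm with spring and autumn maxima.
#'
#' @param year_start,year_end Calendar year range (inclusive).
#' @param latitude Degrees north (used for day length).
#' @param tx_mean,tx_amp Annual mean and seasonal half-amplitude of daily
#'   maximum temperature (degC).
#' @param tn_mean,tn_amp Same for minimum temperature (degC).
#' @param ar1 AR(1) coefficient of the daily temperature anomaly, in [0, 1).
#' @param noise_sd Innovation standard deviation of the anomaly (degC).
#' @param trend Warming trend applied to TX and TN (degC per decade).
#' @param p_wet_wet,p_wet_dry Markov transition probabilities
#'   P(wet | wet yesterday) and P(wet | dry yesterday).
#' @param gamma_shape,gamma_scale Gamma parameters of wet-day amounts (mm).
#' @param wet_month_mult Twelve monthly multipliers on the wet
#'   probabilities (spring/autumn maxima by default).
#' @param ss_clear Fraction of astronomical day length sunny on a clear
#'   day.
#' @param ss_tx,ss_wet Sunshine response (h per degC of anomaly; h lost on
#'   a wet day).
#' @param cc_base,cc_tx,cc_wet Cloud fraction baseline and responses.
#' @param hr_base,hr_tx,hr_wet Relative-humidity baseline (%) and
#'   responses.
#' @param cc_units `"fraction"` (default) or `"oktas"` for the cloud
#'   metadata attribute.
#' @return A validated list of class `weather_gen_config`.
#' @export
weather_gen_config <- function(year_start = 1993L, year_end = 2017L,
                               latitude = 42.45,
                               tx_mean = 18.3, tx_amp = 10.5,
                               tn_mean = 7.8, tn_amp = 7.0,
                               ar1 = 0.7, noise_sd = 2.0,
                               trend = 0.4,
                               p_wet_wet = 0.45, p_wet_dry = 0.22,
                               gamma_shape = 0.8, gamma_scale = 4.934,
                               wet_month_mult = c(0.90, 0.85, 0.95, 1.25,
                                                  1.30, 0.95, 0.55, 0.60,
                                                  0.85, 1.20, 1.25, 1.00),
                               ss_clear = 0.7, ss_tx = 0.35, ss_wet = 3.5,
                               cc_base = 0.45, cc_tx = -0.03, cc_wet = 0.30,
                               hr_base = 62, hr_tx = -2.2, hr_wet = 18,
                               cc_units = c("fraction", "oktas")) {
  cc_units <- match.arg(cc_units)
  cfg <- list(year_start = as.integer(year_start),
              year_end = as.integer(year_end), latitude = latitude,
              tx_mean = tx_mean, tx_amp = tx_amp,
              tn_mean = tn_mean, tn_amp = tn_amp,
              ar1 = ar1, noise_sd = noise_sd, trend = trend,
              p_wet_wet = p_wet_wet, p_wet_dry = p_wet_dry,
              gamma_shape = gamma_shape, gamma_scale = gamma_scale,
              wet_month_mult = wet_month_mult,
              ss_clear = ss_clear, ss_tx = ss_tx, ss_wet = ss_wet,
              cc_base = cc_base, cc_tx = cc_tx, cc_wet = cc_wet,
              hr_base = hr_base, hr_tx = hr_tx, hr_wet = hr_wet,
              cc_units = cc_units)
  if (cfg$year_end < cfg$year_start)
    stop("configuration error: year_end must be >= year_start")
  probs <- c(cfg$p_wet_wet, cfg$p_wet_dry,
             pmin(1, cfg$wet_month_mult * max(cfg$p_wet_wet, cfg$p_wet_dry)))
  if (any(c(cfg$p_wet_wet, cfg$p_wet_dry) < 0) ||
      any(c(cfg$p_wet_wet, cfg$p_wet_dry) > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (any(cfg$wet_month_mult < 0))
    stop("configuration error: monthly multipliers must be >= 0")
  if (cfg$gamma_shape <= 0 || cfg$gamma_scale <= 0)
    stop("configuration error: gamma shape and scale must be > 0")
  if (cfg$ar1 < 0 || cfg$ar1 >= 1)
    stop("configuration error: AR(1) coefficient must be in [0, 1)")
  if (cfg$noise_sd < 0) stop("configuration error: noise sd must be >= 0")
  class(cfg) <- "weather_gen_config"
  cfg
}

# Astronomical day length (hours) for a vector of days-of-year.
.day_length <- function(doy, latitude) {
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  phi <- latitude * pi / 180
  cos_ws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 / pi * acos(cos_ws)
}

#' Generate a daily station weather series
#'
#' Seasonal cycle: a cosine peaking in late July (day-of-year 205).
#' Temperature anomalies are a shared AR(1) process (TX and TN move
#' together, as daily anomalies do) plus independent noise on the diurnal
#' range; TN is clamped below TX so tx >= tn holds on every day.
#' Precipitation occurrence follows a two-state Markov chain whose wet
#' probabilities are scaled by monthly multipliers; wet-day amounts are
#' gamma distributed. Sunshine, cloud cover and relative humidity are
#' linear responses to the temperature anomaly and the wet/dry state,
#' clipped to their physical ranges.
#'
#' @param config A [weather_gen_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical series.
#' @return A daily weather series data.frame (`date`, `tx`, `tn`, `pp`,
#'   `ss`, `cc`, `hr`) with attribute `cc_units`; passes
#'   [validate_daily_weather()].
#' @export
generate_daily_weather <- function(config = weather_gen_config(), seed = 1L) {
  stopifnot(inherits(config, "weather_gen_config"))
  set.seed(as.integer(seed))

  dates <- seq(as.Date(sprintf("%d-01-01", config$year_start)),
               as.Date(sprintf("%d-12-31", config$year_end)), by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  mo <- .month(dates)
  frac_decade <- (as.integer(dates) - as.integer(dates[1])) / 3652.5

  season <- cos(2 * pi * (doy - 205) / 365.25)
  trend <- config$trend * frac_decade

  # shared AR(1) anomaly, stationary initialisation
  anom <- numeric(n)
  innov <- stats::rnorm(n, 0, config$noise_sd)
  if (config$noise_sd > 0) {
    anom[1] <- stats::rnorm(1, 0, config$noise_sd /
                              sqrt(1 - config$ar1^2))
  }
  for (i in 2:n) anom[i] <- config$ar1 * anom[i - 1] + innov[i]
  range_noise <- stats::rnorm(n, 0, config$noise_sd / 2)

  tx <- config$tx_mean + config$tx_amp * season + trend + anom
  tn <- config$tn_mean + config$tn_amp * season + trend + anom + range_noise
  tn <- pmin(tn, tx)

  # precipitation: Markov occurrence with monthly multipliers
  mult <- config$wet_month_mult[mo]
  p_ww <- pmin(0.99, config$p_wet_wet * mult)
  p_wd <- pmin(0.99, config$p_wet_dry * mult)
  u <- stats::runif(n)
  wet <- logical(n)
  wet[1] <- u[1] < p_wd[1]
  for (i in 2:n) wet[i] <- u[i] < (if (wet[i - 1]) p_ww[i] else p_wd[i])
  pp <- numeric(n)
  nw <- sum(wet)
  if (nw > 0)
    pp[wet] <- stats::rgamma(nw, shape = config$gamma_shape,
                             scale = config$gamma_scale)

  dl <- .day_length(doy, config$latitude)
  ss <- config$ss_clear * dl + config$ss_tx * anom - config$ss_wet * wet
  ss <- pmin(pmax(ss, 0), dl)
  cc <- config$cc_base + config$cc_tx * anom + config$cc_wet * wet
  cc <- pmin(pmax(cc, 0), 1)
  if (config$cc_units == "oktas") cc <- cc * 8
  hr <- config$hr_base + config$hr_tx * anom + config$hr_wet * wet
  hr <- pmin(pmax(hr, 0), 100)

  out <- data.frame(date = dates, tx = tx, tn = tn, pp = pp,
                    ss = ss, cc = cc, hr = hr)
  attr(out, "cc_units") <- config$cc_units
  attr(out, "config") <- config
  attr(out, "seed") <- as.integer(seed)
  validate_daily_weather(out)
  out
}

#' Standardized water-balance proxy for the drought index
#'
#' The drought index consumed downstream is an external product; for
#' synthetic runs this proxy standardizes the monthly climatic water
#' balance (precipitation minus Thornthwaite PET) per calendar month
#' across years. It reproduces the index's scale (zero mean, unit
#' variance per month) but not its multi-scalar accumulation or
#' distribution fitting.
#'
#' @param weather Daily weather series.
#' @param latitude Degrees north, for PET.
#' @return data.frame `year`, `month`, `value`.
#' @export
generate_spei_proxy <- function(weather, latitude = 42.45) {
  monthly <- aggregate_monthly(weather)
  years <- sort(unique(monthly$year))
  years <- years[vapply(years, function(y) sum(monthly$year == y) == 12L,
                        logical(1))]
  monthly <- monthly[monthly$year %in% years, , drop = FALSE]
  monthly <- monthly[order(monthly$year, monthly$month), , drop = FALSE]
  pet <- unlist(lapply(years, function(y) {
    my <- monthly[monthly$year == y, ]
    thornthwaite_pet((my$tx + my$tn) / 2, latitude, y)
  }))
  wb <- monthly$pp_total - pet
  z <- numeric(length(wb))
  for (m in 1:12) {
    sel <- monthly$month == m
    s <- stats::sd(wb[sel])
    z[sel] <- if (is.finite(s) && s > 0) (wb[sel] - mean(wb[sel])) / s else 0
  }
  data.frame(year = monthly$year, month = monthly$month, value = z)
}
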