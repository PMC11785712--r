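#' @keywords internal
"_PACKAGE"

# ---- daily weather series validation -----------------------------------

#' Validate a daily weather series
#'
#' A daily weather series is a data.frame with columns `date` (Date,
#' strictly increasing, gap-free), `tx`/`tn` (max/min temperature, degC),
#' `pp` (precipitation, mm/day), `ss` (sunshine hours/day), `cc` (cloud
#' cover, fraction or oktas — declared by the `cc_units` attribute) and
#' `hr` (relative humidity, %). Invariants checked: tx >= tn, pp >= 0,
#' hr in [0, 100], no calendar gaps.
#'
#' @param daily Candidate data.frame.
#' @return `daily` invisibly; errors name the offending row.
#' @export
validate_daily_weather <- function(daily) {
  need <- c("date", "tx", "tn", "pp", "ss", "cc", "hr")
  miss <- setdiff(need, names(daily))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!inherits(daily$date, "Date")) stop("column 'date' must be of class Date")
  d <- diff(as.integer(daily$date))
  if (any(d <= 0)) stop("dates must be strictly increasing (row ",
                        which(d <= 0)[1] + 1L, ")")
  if (any(d > 1)) stop("gap in daily coverage after row ", which(d > 1)[1])
  bad <- which(daily$tx < daily$tn)
  if (length(bad)) stop("tx < tn at row ", bad[1], " (", daily$date[bad[1]], ")")
  bad <- which(daily$pp < 0)
  if (length(bad)) stop("negative precipitation at row ", bad[1])
  bad <- which(daily$hr < 0 | daily$hr > 100)
  if (length(bad)) stop("relative humidity outside [0,100] at row ", bad[1])
  invisible(daily)
}

.year  <- function(dates) as.integer(format(dates, "%Y"))
.month <- function(dates) as.integer(format(dates, "%m"))

.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- if (month == 12L) as.Date(sprintf("%d-01-01", year + 1L))
         else as.Date(sprintf("%d-%02d-01", year, month + 1L))
  as.integer(nxt - first)
}

# ---- monthly aggregation -----------------------------------------------

#' Aggregate daily station data to monthly values
#'
#' Means for tx/tn/cc/hr, both mean and sum for sunshine, totals for
#' precipitation. Months not fully covered by the series are excluded
#' (with a warning) unless `allow_partial = TRUE`.
#'
#' @param daily Daily weather series (see [validate_daily_weather()]).
#' @param allow_partial Keep months with missing days?
#' @return data.frame with `year`, `month`, `tx`, `tn`, `cc`, `hr`, `ss`
#'   (mean hours/day), `ss_total`, `pp_total`, `n_days`, `wet_days`
#'   (days with pp > 1 mm).
#' @export
aggregate_monthly <- function(daily, allow_partial = FALSE) {
  validate_daily_weather(daily)
  yr <- .year(daily$date); mo <- .month(daily$date)
  key <- yr * 100L + mo
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  u <- sort(unique(key))
  out <- data.frame(
    year = u %/% 100L, month = u %% 100L,
    tx = agg(daily$tx, mean), tn = agg(daily$tn, mean),
    cc = agg(daily$cc, mean), hr = agg(daily$hr, mean),
    ss = agg(daily$ss, mean), ss_total = agg(daily$ss, sum),
    pp_total = agg(daily$pp, sum),
    n_days = as.integer(tapply(daily$date, key, length)),
    wet_days = as.integer(tapply(daily$pp, key, function(p) sum(p > 1)))
  )
  full <- mapply(.days_in_month, out$year, out$month)
  partial <- out$n_days < full
  if (any(partial) && !allow_partial) {
    warning(sum(partial), " partial month(s) excluded")
    out <- out[!partial, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# ---- day-count statistics ----------------------------------------------

#' Count hot, frost or wet days
#'
#' Day counts use strict inequalities: hot days (`"HD"`) are tx > 30 degC,
#' frost days (`"FD"`) tn < 0 degC, wet days (`"WD"`) pp > 1 mm.
#'
#' @param daily Daily weather series.
#' @param predicate One of `"HD"`, `"FD"`, `"WD"`.
#' @param months Month window (inclusive), default April-October.
#' @return Named integer vector, one count per year present in the window.
#' @export
count_days <- function(daily, predicate = c("HD", "FD", "WD"), months = 4:10) {
  predicate <- match.arg(predicate)
  validate_daily_weather(daily)
  sel <- .month(daily$date) %in% months
  hit <- switch(predicate,
    HD = daily$tx[sel] > 30,
    FD = daily$tn[sel] < 0,
    WD = daily$pp[sel] > 1
  )
  yr <- .year(daily$date)[sel]
  counts <- tapply(hit, yr, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# ---- thermal indices ---------------------------------------------------

.window_complete <- function(daily, months, allow_partial) {
  yr <- .year(daily$date); mo <- .month(daily$date)
  sel <- mo %in% months
  if (!allow_partial) {
    expected <- function(y) sum(vapply(months, .days_in_month, 0L, year = y))
    got <- tapply(sel, yr, sum)
    for (y in names(got)) {
      if (got[[y]] > 0 && got[[y]] < expected(as.integer(y)))
        stop("year ", y, " does not cover the full month window; ",
             "use allow_partial = TRUE to override")
    }
  }
  sel
}

#' Growing Degree Days
#'
#' Accumulated daily mean temperature above a base over the growing
#' season: \eqn{\sum \max(0, (tx+tn)/2 - base)}. Defaults: April-October
#' window, 10 degC base.
#'
#' @param daily Daily weather series.
#' @param months Month window, default `4:10`.
#' @param base Base temperature, degC.
#' @param allow_partial Tolerate incomplete windows?
#' @return Named numeric vector (degree-days), one per year.
#' @export
growing_degree_days <- function(daily, months = 4:10, base = 10,
                                allow_partial = FALSE) {
  validate_daily_weather(daily)
  sel <- .window_complete(daily, months, allow_partial)
  tm <- (daily$tx[sel] + daily$tn[sel]) / 2
  g <- tapply(pmax(0, tm - base), .year(daily$date)[sel], sum)
  out <- as.numeric(g); names(out) <- names(g)
  out
}

# Huglin day-length coefficient: stepwise table by absolute latitude with
# linear interpolation between rows; flat below 40 deg, 1.06 for 48-50 deg.
huglin_k <- function(latitude) {
  if (abs(latitude) > 60) stop("latitude outside [-60, 60]")
  al <- abs(latitude)
  if (al > 50) stop("latitude outside the Huglin coefficient table (|lat| <= 50)")
  if (al <= 40) return(1.02)
  if (al >= 48) return(1.06)
  stats::approx(c(40, 42, 44, 46, 48),
                c(1.02, 1.03, 1.04, 1.05, 1.06), xout = al)$y
}

#' Huglin heliothermal index
#'
#' \eqn{HI = \sum_{Apr 1}^{Sep 30} K \max(0, ((T_{mean}-10)+(TX-10))/2)}
#' with K the latitude-dependent day-length coefficient (about 1.03 at
#' 42.45 degrees N) and \eqn{T_{mean} = (TX+TN)/2}.
#'
#' @inheritParams growing_degree_days
#' @param latitude Degrees north; the coefficient table covers |lat| <= 50.
#' @return Named numeric vector of Huglin units, one per year.
#' @export
huglin_index <- function(daily, latitude, months = 4:9,
                         allow_partial = FALSE) {
  validate_daily_weather(daily)
  K <- huglin_k(latitude)
  sel <- .window_complete(daily, months, allow_partial)
  tm <- (daily$tx[sel] + daily$tn[sel]) / 2
  term <- pmax(0, ((tm - 10) + (daily$tx[sel] - 10)) / 2)
  h <- tapply(K * term, .year(daily$date)[sel], sum)
  out <- as.numeric(h); names(out) <- names(h)
  out
}

#' Cool Night Index
#'
#' Mean September minimum temperature (degC), a ripening-period
#' night-coolness measure.
#'
#' @param daily Daily weather series.
#' @return Named numeric vector, one value per year with September data.
#' @export
cool_night_index <- function(daily) {
  validate_daily_weather(daily)
  sel <- .month(daily$date) == 9L
  ci <- tapply(daily$tn[sel], .year(daily$date)[sel], mean)
  out <- as.numeric(ci); names(out) <- names(ci)
  out
}

# ---- dryness index -----------------------------------------------------

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite PET from monthly mean temperature and latitude:
#' annual heat index \eqn{I = \sum (T/5)^{1.514}} over months with T > 0,
#' exponent \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 +
#' 1.7912\times10^{-2} I + 0.49239}, and
#' \eqn{PET = 16 (L/12)(N/30)(10T/I)^a} mm/month, with L the mean day
#' length (hours) and N the number of days in the month.
#'
#' @param tmean Numeric vector of 12 monthly mean temperatures (degC,
#'   January-December).
#' @param latitude Degrees north.
#' @param year Calendar year (for month lengths); default a non-leap year.
#' @return Numeric vector of 12 monthly PET values (mm).
#' @export
thornthwaite_pet <- function(tmean, latitude, year = 2001L) {
  if (length(tmean) != 12L) stop("tmean must have 12 monthly values")
  I <- sum(pmax(tmean, 0)[tmean > 0]^1.514 / 5^1.514)
  if (I <= 0) return(rep(0, 12))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.7912e-2 * I + 0.49239
  mid_doy <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  decl <- 0.409 * sin(2 * pi / 365 * mid_doy - 1.39)
  phi <- latitude * pi / 180
  cos_ws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  L <- 24 / pi * acos(cos_ws)
  N <- vapply(1:12, .days_in_month, 0L, year = as.integer(year))
  pet <- ifelse(tmean > 0,
                16 * (L / 12) * (N / 30) * (10 * tmean / I)^a, 0)
  pet
}

#' Dryness Index
#'
#' End-of-September potential soil-water reserve from the monthly vine
#' water balance over April-September. Starting from an initial reserve
#' of `w0` = 200 mm, each month updates
#' \eqn{W \leftarrow \min(w0,\; W + P - T_v - E_s)} with vine
#' transpiration \eqn{T_v = k \cdot PET}, bare-soil evaporation
#' \eqn{E_s = (PET/N)(1-k)\,JPm}, monthly radiation-interception
#' coefficient k = 0.1 (April), 0.3 (May), 0.5 (June-September), N the
#' days in the month and JPm = min(N/5, wet-day count) the effective
#' soil-evaporation days. W is capped above at `w0` but may go negative,
#' as the index's viticultural class limits require.
#'
#' @param p Numeric vector of 6 monthly precipitation totals (mm),
#'   April-September.
#' @param pet Numeric vector of 6 monthly PET values (mm), April-September.
#' @param jpm Optional vector of 6 wet-day counts; when `NULL` the N/5
#'   default is used for every month.
#' @param w0 Initial (and maximum) soil-water reserve, mm.
#' @param year Calendar year, for month lengths.
#' @return The end-of-September reserve W (mm), a scalar.
#' @export
dryness_index <- function(p, pet, jpm = NULL, w0 = 200, year = 2001L) {
  if (length(p) != 6L || length(pet) != 6L)
    stop("p and pet must cover the 6 months April-September")
  if (any(pet < 0)) stop("PET must be non-negative")
  k <- c(0.1, 0.3, 0.5, 0.5, 0.5, 0.5)
  N <- vapply(4:9, .days_in_month, 0L, year = as.integer(year))
  if (is.null(jpm)) jpm <- N / 5
  jpm <- pmin(N / 5, jpm)
  W <- w0
  for (m in 1:6) {
    Tv <- k[m] * pet[m]
    Es <- (pet[m] / N[m]) * (1 - k[m]) * jpm[m]
    W <- min(w0, W + p[m] - Tv - Es)
  }
  W
}

# ---- SPEI window extraction --------------------------------------------

#' Extract seasonal SPEI windows
#'
#' The drought index is consumed, never computed: given a monthly SPEI
#' series, this returns the three seasonal summaries used downstream —
#' the mean over July-September (summer), over March-September (the
#' growing season; note the 7-month window despite the conventional
#' "6" label), and over October of the previous year through September.
#'
#' @param spei data.frame with columns `year`, `month`, `value`.
#' @param year Target calendar year.
#' @return Named numeric vector `c(spei3, spei6, spei12)`.
#' @export
spei_windows <- function(spei, year) {
  stopifnot(all(c("year", "month", "value") %in% names(spei)))
  pick <- function(sel) {
    if (length(sel) == 0L) stop("SPEI window not covered for year ", year)
    mean(spei$value[sel])
  }
  s3 <- pick(which(spei$year == year & spei$month %in% 7:9))
  s6 <- pick(which(spei$year == year & spei$month %in% 3:9))
  s12 <- pick(c(which(spei$year == year - 1 & spei$month %in% 10:12),
                which(spei$year == year & spei$month %in% 1:9)))
  c(spei3 = s3, spei6 = s6, spei12 = s12)
}

# ---- per-year summary table --------------------------------------------

#' Annual bioclimatic index table
#'
#' One row per full calendar year: Growing Degree Days, Huglin index,
#' Cool Night Index, Dryness Index (Thornthwaite PET unless a `pet`
#' function is supplied), hot/frost/wet day counts and accumulated
#' precipitation over the April-October growing season, growing-season
#' means of the base variables, and the SPEI window summaries when a
#' monthly SPEI series is given.
#'
#' @param daily Daily weather series.
#' @param latitude Station latitude, degrees north (default 42.45, the
#'   Rioja reference).
#' @param spei Optional monthly SPEI data.frame (`year`, `month`, `value`).
#' @param pet Function `(tmean12, latitude, year) -> pet12`; default
#'   [thornthwaite_pet()].
#' @return data.frame with columns `year`, `gdd`, `hi`, `ci`, `di`, `hd`,
#'   `fd`, `wd`, `pp_total`, `tx_gs`, `tn_gs`, `ss_gs`, `cc_gs`, `hr_gs`
#'   and (if `spei` given) `spei3`, `spei6`, `spei12`.
#' @export
bioclim_table <- function(daily, latitude = 42.45, spei = NULL,
                          pet = thornthwaite_pet) {
  monthly <- aggregate_monthly(daily)
  years <- sort(unique(monthly$year))
  years <- years[vapply(years, function(y) sum(monthly$year == y) == 12L,
                        logical(1))]
  if (length(years) == 0L) stop("no complete calendar years in the series")
  daily <- daily[.year(daily$date) %in% years, , drop = FALSE]

  gdd <- growing_degree_days(daily)
  hi <- huglin_index(daily, latitude)
  ci <- cool_night_index(daily)
  hd <- count_days(daily, "HD")
  fd <- count_days(daily, "FD")
  wd <- count_days(daily, "WD")

  gs <- monthly[monthly$month %in% 4:10, , drop = FALSE]
  gs_mean <- function(col) as.numeric(tapply(gs[[col]], gs$year, mean))
  pp_total <- as.numeric(tapply(gs$pp_total, gs$year, sum))

  di <- vapply(years, function(y) {
    my <- monthly[monthly$year == y, , drop = FALSE]
    my <- my[order(my$month), , drop = FALSE]
    tmean12 <- (my$tx + my$tn) / 2
    pet12 <- pet(tmean12, latitude, y)
    dryness_index(p = my$pp_total[4:9], pet = pet12[4:9],
                  jpm = my$wet_days[4:9], year = y)
  }, numeric(1))

  out <- data.frame(
    year = years,
    gdd = as.numeric(gdd[as.character(years)]),
    hi = as.numeric(hi[as.character(years)]),
    ci = as.numeric(ci[as.character(years)]),
    di = di,
    hd = as.integer(hd[as.character(years)]),
    fd = as.integer(fd[as.character(years)]),
    wd = as.integer(wd[as.character(years)]),
    pp_total = pp_total,
    tx_gs = gs_mean("tx"), tn_gs = gs_mean("tn"),
    ss_gs = gs_mean("ss"), cc_gs = gs_mean("cc"), hr_gs = gs_mean("hr")
  )
  if (!is.null(spei)) {
    sw <- t(vapply(years, function(y) {
      tryCatch(spei_windows(spei, y),
               error = function(e) c(spei3 = NA_real_, spei6 = NA_real_,
                                     spei12 = NA_real_))
    }, numeric(3)))
    out$spei3 <- sw[, "spei3"]; out$spei6 <- sw[, "spei6"]
    out$spei12 <- sw[, "spei12"]
  }
  out
}
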