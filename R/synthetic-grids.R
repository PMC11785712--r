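# Generators for gridded and large-scale inputs: a vineyard LAI grid with
# a double-logistic annual cycle negatively coupled to summer heat, four
# AR(1) teleconnection indices with an optional imposed May-EA/May-TX
# coupling, and an SST field driven by a fixed dipole-like spatial pattern.

#' LAI grid generator configuration
#'
#' The annual cycle is a double-logistic curve: green-up in April,
#' senescence in October, matching the vegetative cycle of Mediterranean
#' vineyards (dormant November-March, peak canopy in summer). Summer
#' (June-August) values receive an anomaly `coupling` times the
#' standardized summer TX anomaly of the driving weather series, so a
#' negative coupling reproduces the heat-reduces-canopy signal.
#'
#' @param nlat,nlon Grid dimensions (>= 2 each).
#' @param lat0,lon0 Coordinates of the first pixel center (degrees).
#' @param resolution Pixel size, degrees (default the native 0.0727273).
#' @param lai_min,lai_max Dormant and peak LAI (m^2/m^2).
#' @param green_doy,sen_doy Day-of-year of mid green-up and mid
#'   senescence.
#' @param k_green,k_sen Logistic steepnesses (1/day).
#' @param coupling Response of the summer LAI anomaly per sd of summer TX.
#' @param noise_sd Pixel-month noise sd (m^2/m^2).
#' @param fractions Optional numeric vector of vineyard fractions, length
#'   `nlat * nlon`; default a fixed gradient with about half the pixels
#'   above 0.75.
#' @return List of class `lai_gen_config`.
#' @export
lai_gen_config <- function(nlat = 4L, nlon = 4L, lat0 = 42.3, lon0 = -2.6,
                           resolution = 0.0727273,
                           lai_min = 0.3, lai_max = 2.2,
                           green_doy = 110, sen_doy = 285,
                           k_green = 0.08, k_sen = 0.07,
                           coupling = -0.3, noise_sd = 0.08,
                           fractions = NULL) {
  if (nlat < 2L || nlon < 2L) stop("configuration error: grid must be >= 2 x 2")
  np <- nlat * nlon
  if (is.null(fractions))
    fractions <- rep(c(0.85, 0.60, 0.92, 0.78, 0.40, 0.81, 0.70, 0.95),
                     length.out = np)
  if (length(fractions) != np)
    stop("configuration error: fraction table must cover all pixels")
  if (any(fractions < 0 | fractions > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  structure(list(nlat = nlat, nlon = nlon, lat0 = lat0, lon0 = lon0,
                 resolution = resolution, lai_min = lai_min,
                 lai_max = lai_max, green_doy = green_doy, sen_doy = sen_doy,
                 k_green = k_green, k_sen = k_sen, coupling = coupling,
                 noise_sd = noise_sd, fractions = fractions),
            class = "lai_gen_config")
}

.mid_month_doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)

.lai_cycle <- function(cfg) {
  d <- .mid_month_doy
  up <- 1 / (1 + exp(-cfg$k_green * (d - cfg$green_doy)))
  down <- 1 / (1 + exp(cfg$k_sen * (d - cfg$sen_doy)))
  cfg$lai_min + (cfg$lai_max - cfg$lai_min) * up * down
}

#' Generate a monthly LAI grid coupled to summer heat
#'
#' @param config A [lai_gen_config()].
#' @param weather Daily weather series providing the summer (Jun-Aug) TX
#'   anomaly driver and the year range.
#' @param seed Integer seed.
#' @return A [monthly_grid()] of LAI (clamped >= 0) with attributes
#'   `fractions` (the vineyard-fraction data.frame: `pixel`, `lat`, `lon`,
#'   `fraction`) and `coupling` for recovery tests.
#' @export
generate_lai_grid <- function(config = lai_gen_config(), weather,
                              seed = 1L) {
  stopifnot(inherits(config, "lai_gen_config"))
  set.seed(as.integer(seed))
  monthly <- aggregate_monthly(weather)
  years <- sort(unique(monthly$year))
  years <- years[vapply(years, function(y) sum(monthly$year == y) == 12L,
                        logical(1))]
  ny <- length(years)
  summer_tx <- vapply(years, function(y)
    mean(monthly$tx[monthly$year == y & monthly$month %in% 6:8]), numeric(1))
  s <- stats::sd(summer_tx)
  z <- if (is.finite(s) && s > 0) (summer_tx - mean(summer_tx)) / s
       else rep(0, ny)

  np <- config$nlat * config$nlon
  cyc <- .lai_cycle(config)
  nt <- ny * 12L
  yr <- rep(years, each = 12L); mo <- rep(1:12, ny)
  base <- rep(cyc, ny)                       # per time step
  anom <- ifelse(mo %in% 6:8, config$coupling * z[match(yr, years)], 0)
  vm <- matrix(base + anom, nrow = nt, ncol = np) +
    matrix(stats::rnorm(nt * np, 0, config$noise_sd), nt, np)
  vm <- pmax(vm, 0)

  lat <- config$lat0 + (seq_len(config$nlat) - 1) * config$resolution
  lon <- config$lon0 + (seq_len(config$nlon) - 1) * config$resolution
  grid <- monthly_grid(array(vm, c(nt, config$nlat, config$nlon)),
                       year = yr, month = mo, lat = lat, lon = lon,
                       varname = "lai", units = "m2/m2")
  px <- expand.grid(lat = lat, lon = lon)
  attr(grid, "fractions") <- data.frame(pixel = seq_len(np),
                                        lat = px$lat, lon = px$lon,
                                        fraction = config$fractions)
  attr(grid, "coupling") <- config$coupling
  attr(grid, "seed") <- as.integer(seed)
  grid
}

#' Generate monthly teleconnection indices
#'
#' Four standardized AR(1) monthly series (NAO, EA, EA/WR, SCAND). An
#' optional coupling replaces the May value of the EA series with
#' `coupling * may_tx_z + sqrt(1 - coupling^2) * original`, imposing a
#' known May-EA/May-TX correlation for end-to-end recovery tests.
#'
#' @param year_start,year_end Year range.
#' @param ar1 AR(1) coefficient, in [0, 1); innovations are scaled so the
#'   marginal variance is 1.
#' @param coupling Imposed correlation between May EA and the May TX
#'   anomaly, in [-1, 1].
#' @param may_tx_z Standardized May TX anomaly per year (required when
#'   `coupling != 0`; length must match the year range).
#' @param seed Integer seed.
#' @return data.frame `year`, `month`, `nao`, `ea`, `eawr`, `scand`.
#' @export
generate_teleconnection_indices <- function(year_start = 1993L,
                                            year_end = 2017L,
                                            ar1 = 0.3, coupling = 0,
                                            may_tx_z = NULL, seed = 1L) {
  if (ar1 < 0 || ar1 >= 1)
    stop("configuration error: AR coefficient must be in [0, 1)")
  if (abs(coupling) > 1) stop("configuration error: |coupling| must be <= 1")
  set.seed(as.integer(seed))
  years <- year_start:year_end
  n <- length(years) * 12L
  gen <- function() {
    innov_sd <- sqrt(1 - ar1^2)
    x <- numeric(n)
    x[1] <- stats::rnorm(1)
    e <- stats::rnorm(n, 0, innov_sd)
    for (i in 2:n) x[i] <- ar1 * x[i - 1] + e[i]
    x
  }
  out <- data.frame(year = rep(years, each = 12L),
                    month = rep(1:12, length(years)),
                    nao = gen(), ea = gen(), eawr = gen(), scand = gen())
  if (coupling != 0) {
    if (is.null(may_tx_z) || length(may_tx_z) != length(years))
      stop("may_tx_z (one value per year) is required when coupling != 0")
    may <- out$month == 5L
    out$ea[may] <- coupling * may_tx_z +
      sqrt(1 - coupling^2) * out$ea[may]
  }
  out
}

#' SST field generator configuration
#'
#' The spatial structure is a fixed dipole-like pattern (two Gaussian
#' lobes of opposite sign, an idealised ENSO-type mode); each month's
#' field is `pattern * coupling * driver(year) + noise`, where December
#' is attributed to the following year's previous-December-to-May window.
#'
#' @param nlat,nlon Grid dimensions.
#' @param lat,lon Optional explicit axes; defaults span a tropical band.
#' @param coupling Scalar coupling between driver and field.
#' @param noise_sd Pixel-month noise sd (degC).
#' @param pattern Optional nlat x nlon pattern matrix; default the dipole.
#' @return List of class `sst_gen_config`.
#' @export
sst_gen_config <- function(nlat = 9L, nlon = 18L, lat = NULL, lon = NULL,
                           coupling = -0.5, noise_sd = 0.5,
                           pattern = NULL) {
  if (is.null(lat)) lat <- seq(-20, 20, length.out = nlat)
  if (is.null(lon)) lon <- seq(-180, 179, length.out = nlon)
  if (length(lat) != nlat || length(lon) != nlon)
    stop("shape error: axes do not match grid dimensions")
  if (is.null(pattern)) {
    g <- function(la, lo, la0, lo0, s)
      exp(-(((la - la0) / s[1])^2 + ((lo - lo0) / s[2])^2))
    px <- expand.grid(lat = lat, lon = lon)
    pattern <- matrix(g(px$lat, px$lon, 0, -120, c(12, 40)) -
                        g(px$lat, px$lon, 0, 140, c(12, 40)),
                      nlat, nlon)
  }
  if (!all(dim(pattern) == c(nlat, nlon)))
    stop("shape error: pattern must be nlat x nlon")
  structure(list(nlat = nlat, nlon = nlon, lat = lat, lon = lon,
                 coupling = coupling, noise_sd = noise_sd,
                 pattern = pattern),
            class = "sst_gen_config")
}

#' Generate a monthly SST field from an annual driver
#'
#' `SST(t, x) = pattern(x) * coupling * driver(year(t)) + noise`, with
#' December assigned the next year's driver so the
#' previous-December-to-May seasonal mean recovers
#' `pattern * coupling * driver` exactly when `noise_sd = 0`.
#'
#' @param config An [sst_gen_config()].
#' @param driver_series Named-by-year numeric vector (one value per year)
#'   or a data.frame with `year` and `value`.
#' @param seed Integer seed.
#' @return A [monthly_grid()] with attributes `pattern` (the ground-truth
#'   spatial mode) and `coupling`.
#' @export
generate_sst_field <- function(config = sst_gen_config(), driver_series,
                               seed = 1L) {
  stopifnot(inherits(config, "sst_gen_config"))
  if (is.data.frame(driver_series)) {
    years <- driver_series$year
    drv <- driver_series$value
  } else {
    if (is.null(names(driver_series)))
      stop("driver_series must be a data.frame(year, value) or named by year")
    years <- as.integer(names(driver_series))
    drv <- as.numeric(driver_series)
  }
  if (length(years) != length(drv)) stop("shape error: driver length mismatch")
  set.seed(as.integer(seed))

  ny <- length(years)
  yr <- rep(years, each = 12L); mo <- rep(1:12, ny)
  eff_year <- ifelse(mo == 12L, yr + 1L, yr)
  d <- drv[match(eff_year, years)]
  d[is.na(d)] <- 0          # December of the final year drives no window
  np <- config$nlat * config$nlon
  nt <- ny * 12L
  vm <- outer(config$coupling * d, as.numeric(config$pattern)) +
    matrix(stats::rnorm(nt * np, 0, config$noise_sd), nt, np)
  grid <- monthly_grid(array(vm, c(nt, config$nlat, config$nlon)),
                       year = yr, month = mo,
                       lat = config$lat, lon = config$lon,
                       varname = "sst", units = "degC")
  attr(grid, "pattern") <- config$pattern
  attr(grid, "coupling") <- config$coupling
  attr(grid, "seed") <- as.integer(seed)
  grid
}
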