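# Gridded monthly fields (LAI, SST) and their spatial operations: pixel
# geometry, vineyard-pixel selection, regional phenology series, seasonal
# windowed means and correlation maps with analytic significance masking.

#' Construct a gridded monthly series
#'
#' Container for a (time, lat, lon) monthly field. Pixels are indexed in
#' column-major order over `expand.grid(lat = lat, lon = lon)` (latitude
#' varying fastest), which is also the row order of vineyard-fraction
#' tables.
#'
#' @param values Numeric array of dim `c(n_time, n_lat, n_lon)`.
#' @param year,month Integer vectors of length `n_time`.
#' @param lat,lon Pixel-center coordinates (degrees); strictly monotone.
#'   Longitudes in [-180, 180).
#' @param varname,units Metadata strings.
#' @return Object of class `monthly_grid`.
#' @export
monthly_grid <- function(values, year, month, lat, lon,
                         varname = "value", units = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  nt <- dim(values)[1]
  if (length(year) != nt || length(month) != nt)
    stop("time axis mismatch: year/month must have length dim(values)[1]")
  if (dim(values)[2] != length(lat) || dim(values)[3] != length(lon))
    stop("shape error: spatial axes do not match the value array")
  mono <- function(x) length(x) < 2L || all(diff(x) > 0) || all(diff(x) < 0)
  if (!mono(lat)) stop("lat axis must be strictly monotone")
  if (!mono(lon)) stop("lon axis must be strictly monotone")
  structure(list(values = values, year = as.integer(year),
                 month = as.integer(month), lat = lat, lon = lon,
                 varname = varname, units = units),
            class = "monthly_grid")
}

#' @export
print.monthly_grid <- function(x, ...) {
  cat(sprintf("monthly_grid '%s' [%s]: %d time steps (%d-%d), %d x %d pixels\n",
              x$varname, x$units, length(x$year), min(x$year), max(x$year),
              length(x$lat), length(x$lon)))
  invisible(x)
}

# time-major matrix view: one column per pixel, lat varying fastest
.grid_matrix <- function(grid) matrix(grid$values, nrow = length(grid$year))

#' Pixel area on a spherical Earth
#'
#' Area of a square pixel of angular size `resolution_deg` centred at
#' `latitude`: \eqn{(res \cdot L)^2 \cos(\phi)} with
#' \eqn{L = \pi R / 180} km per degree and R = 6371 km. At the native
#' 0.0727273-degree resolution and 42.45 degrees N this is ~48.3 km^2.
#'
#' @param resolution_deg Pixel size in degrees.
#' @param latitude Latitude of interest, degrees.
#' @return Area in km^2.
#' @examples
#' pixel_area(0.0727273, 42.45)
#' @export
pixel_area <- function(resolution_deg, latitude) {
  L <- pi * 6371 / 180
  (resolution_deg * L)^2 * cos(latitude * pi / 180)
}

#' Select vineyard-dominated pixels
#'
#' Keeps pixels whose vineyard land-cover fraction is at least the
#' threshold ("a minimum of 75%" reads as inclusive).
#'
#' @param fractions data.frame with columns `pixel`, `lat`, `lon`,
#'   `fraction` (in [0, 1]).
#' @param threshold Minimum fraction, default 0.75.
#' @return Logical vector aligned with the rows of `fractions`; warns if
#'   no pixel qualifies.
#' @export
select_vineyard_pixels <- function(fractions, threshold = 0.75) {
  stopifnot("fraction" %in% names(fractions))
  f <- fractions$fraction
  if (any(f < 0 | f > 1)) stop("configuration error: fractions must lie in [0, 1]")
  mask <- f >= threshold
  if (!any(mask)) warning("no pixel meets the vineyard-fraction threshold")
  mask
}

#' Regional LAI series over selected pixels
#'
#' Unweighted mean over the masked pixels for every month, plus an
#' annual-cycle summary (per-calendar-month mean and standard deviation
#' across years). Feeds [composite_report()] for phenology composites.
#'
#' @param grid A [monthly_grid()].
#' @param mask Logical vector over pixels (length n_lat * n_lon, latitude
#'   varying fastest), e.g. from [select_vineyard_pixels()].
#' @param weights Optional per-pixel weights (e.g. areas); default
#'   unweighted.
#' @return List with `series` (data.frame `year`, `month`, `value`) and
#'   `annual_cycle` (data.frame `month`, `mean`, `sd`).
#' @export
regional_lai_series <- function(grid, mask, weights = NULL) {
  stopifnot(inherits(grid, "monthly_grid"))
  vm <- .grid_matrix(grid)
  if (length(mask) != ncol(vm)) stop("mask length must equal the pixel count")
  if (!any(mask)) stop("empty pixel selection")
  sub <- vm[, mask, drop = FALSE]
  if (is.null(weights)) {
    val <- rowMeans(sub)
  } else {
    w <- weights[mask]
    val <- as.numeric(sub %*% w) / sum(w)
  }
  series <- data.frame(year = grid$year, month = grid$month, value = val)
  ac <- data.frame(
    month = 1:12,
    mean = vapply(1:12, function(m) mean(val[grid$month == m]), numeric(1)),
    sd = vapply(1:12, function(m) stats::sd(val[grid$month == m]), numeric(1))
  )
  list(series = series, annual_cycle = ac)
}

#' Seasonal windowed mean of a gridded field
#'
#' Per-pixel mean over a window spanning months of the previous calendar
#' year (default December) and of the target year (default January-May):
#' the previous-December-to-May window used for SST. Years whose
#' previous-year months are missing are dropped.
#'
#' @param grid A [monthly_grid()].
#' @param prev_months Months taken from year t-1.
#' @param cur_months Months taken from year t.
#' @return List with `year`, `values` (matrix year x pixel), `lat`, `lon`.
#' @export
seasonal_sst_mean <- function(grid, prev_months = 12L, cur_months = 1:5) {
  stopifnot(inherits(grid, "monthly_grid"))
  vm <- .grid_matrix(grid)
  years <- sort(unique(grid$year))
  keep <- vapply(years, function(t) {
    all(vapply(prev_months, function(m)
      any(grid$year == t - 1 & grid$month == m), logical(1))) &&
    all(vapply(cur_months, function(m)
      any(grid$year == t & grid$month == m), logical(1)))
  }, logical(1))
  years <- years[keep]
  if (length(years) == 0L) stop("no year has the full seasonal window")
  vals <- t(vapply(years, function(t) {
    rows <- c(which(grid$year == t - 1 & grid$month %in% prev_months),
              which(grid$year == t & grid$month %in% cur_months))
    colMeans(vm[rows, , drop = FALSE])
  }, numeric(ncol(vm))))
  list(year = years, values = vals, lat = grid$lat, lon = grid$lon)
}

.detrend_vec <- function(v, t) {
  ok <- is.finite(v)
  if (sum(ok) < 3) return(rep(NA_real_, length(v)))
  fit <- stats::lm.fit(cbind(1, t[ok]), v[ok])
  out <- rep(NA_real_, length(v))
  out[ok] <- fit$residuals
  out
}

#' Correlation map between an annual index and a gridded field
#'
#' Pearson correlation of the (optionally detrended) index with every
#' pixel's (optionally detrended) annual series, with an analytic
#' significance mask: |r| >= [critical_r()] at the pairwise-complete
#' sample size of each pixel.
#'
#' @param index Numeric annual index, aligned with `table$year`.
#' @param table Output of [seasonal_sst_mean()] (or any list with `year`,
#'   `values` matrix, `lat`, `lon`).
#' @param detrend Remove a linear-in-year trend from index and pixels?
#' @param alpha Significance level for the mask.
#' @return List with matrices `r` and `significant` (n_lat x n_lon),
#'   vector `threshold` and `n` per pixel, and the axes.
#' @export
correlation_map <- function(index, table, detrend = TRUE, alpha = 0.05) {
  years <- table$year
  if (length(index) != length(years))
    stop("index length must match the table's year count")
  idx <- if (detrend) .detrend_vec(index, years) else index
  np <- ncol(table$values)
  r <- numeric(np); n_eff <- integer(np); thr <- numeric(np)
  for (p in seq_len(np)) {
    v <- table$values[, p]
    ok <- is.finite(v) & is.finite(idx)
    n_eff[p] <- sum(ok)
    if (n_eff[p] < 4) { r[p] <- NA_real_; thr[p] <- NA_real_; next }
    vv <- if (detrend) .detrend_vec(v[ok], years[ok]) else v[ok]
    r[p] <- stats::cor(idx[ok], vv)
    thr[p] <- critical_r(n_eff[p], alpha)
  }
  nlat <- length(table$lat); nlon <- length(table$lon)
  list(r = matrix(r, nlat, nlon),
       significant = matrix(abs(r) >= thr, nlat, nlon),
       threshold = thr, n = n_eff, lat = table$lat, lon = table$lon,
       alpha = alpha)
}
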