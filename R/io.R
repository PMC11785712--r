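# Readers and writers for the interchange formats: daily station CSV,
# vintage CSV, CPC-style monthly index text, vineyard-fraction CSV and
# long-format grid CSV (NetCDF read/write available when the ncdf4
# package is installed). All CSVs are UTF-8, comma-separated, ISO-8601
# dates, '.' decimal.

#' Write / read a daily station weather CSV
#'
#' One row per day, columns `date,tx,tn,pp,ss,cc,hr`. Reading validates
#' the physical invariants and reports the first offending row.
#'
#' @param daily Daily weather series.
#' @param path File path.
#' @return `read_station_csv` returns a validated daily weather series.
#' @export
write_station_csv <- function(daily, path) {
  validate_daily_weather(daily)
  df <- daily
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tx", "tn", "pp", "ss", "cc", "hr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema mismatch: missing column(s) ", paste(miss, collapse = ", "))
  d <- as.Date(df$date)
  if (anyNA(d)) stop("unparseable date at row ", which(is.na(d))[1])
  df$date <- d
  validate_daily_weather(df)
  df
}

#' Write / read an annual vintage CSV
#'
#' One row per vintage year; the `rating` column round-trips as an
#' ordered factor (good < very good < excellent).
#'
#' @param table Vintage data.frame.
#' @param path File path.
#' @return `read_vintage_csv` returns the vintage data.frame.
#' @export
write_vintage_csv <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vintage_csv
#' @export
read_vintage_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"year" %in% names(df)) stop("schema mismatch: missing column 'year'")
  bad <- vapply(c("veraison_doy", "harvest_doy"), function(cn) {
    if (!cn %in% names(df)) return(0L)
    w <- which(df[[cn]] < 1 | df[[cn]] > 366)
    if (length(w)) w[1] else 0L
  }, integer(1))
  if (any(bad > 0))
    stop("day-of-year outside [1, 366] at row ", max(bad))
  if ("rating" %in% names(df))
    df$rating <- factor(df$rating,
                        levels = c("good", "very good", "excellent"),
                        ordered = TRUE)
  df
}

#' Write / read a CPC-style monthly index table
#'
#' Whitespace-delimited text, one row per year: the year followed by 12
#' monthly values (January-December), as the Climate Prediction Center
#' distributes teleconnection indices.
#'
#' @param indices data.frame with `year`, `month` and the index column.
#' @param column Which index column to write.
#' @param path File path.
#' @return `read_index_table` returns a long data.frame `year`, `month`,
#'   `value`.
#' @export
write_index_table <- function(indices, column, path) {
  stopifnot(all(c("year", "month", column) %in% names(indices)))
  years <- sort(unique(indices$year))
  lines <- vapply(years, function(y) {
    v <- vapply(1:12, function(m) {
      w <- which(indices$year == y & indices$month == m)
      if (length(w) != 1L) stop("incomplete year ", y, " (month ", m, ")")
      indices[[column]][w]
    }, numeric(1))
    paste(c(sprintf("%d", y), sprintf("%8.3f", v)), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE)
  if (ncol(raw) != 13L)
    stop("schema mismatch: expected 13 columns (year + 12 months), got ",
         ncol(raw))
  data.frame(year = rep(as.integer(raw[[1]]), each = 12L),
             month = rep(1:12, nrow(raw)),
             value = as.numeric(t(as.matrix(raw[, 2:13]))))
}

#' Write / read a vineyard-fraction table
#'
#' CSV with columns `pixel,lat,lon,fraction`; fractions validated into
#' [0, 1] on read.
#'
#' @param fractions data.frame `pixel`, `lat`, `lon`, `fraction`.
#' @param path File path.
#' @return `read_fraction_table` returns the validated data.frame.
#' @export
write_fraction_table <- function(fractions, path) {
  utils::write.csv(fractions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_table
#' @export
read_fraction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel", "lat", "lon", "fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema mismatch: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(df$fraction < 0 | df$fraction > 1)
  if (length(bad)) stop("fraction outside [0, 1] at row ", bad[1])
  df
}

#' Write / read a gridded monthly series as long-format CSV
#'
#' Columns `year,month,lat,lon,value`, one row per (time, pixel). The
#' always-available text interchange format for grids; see
#' [write_grid_netcdf()] for the NetCDF alternative.
#'
#' @param grid A [monthly_grid()].
#' @param path File path.
#' @param varname,units Metadata for the reconstructed grid on read.
#' @return `read_grid_csv` returns a [monthly_grid()].
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "monthly_grid"))
  px <- expand.grid(lat = grid$lat, lon = grid$lon)
  nt <- length(grid$year)
  df <- data.frame(
    year = rep(grid$year, times = nrow(px)),
    month = rep(grid$month, times = nrow(px)),
    lat = rep(px$lat, each = nt),
    lon = rep(px$lon, each = nt),
    value = as.numeric(.grid_matrix(grid))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, varname = "value", units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "lat", "lon", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema mismatch: missing column(s) ", paste(miss, collapse = ", "))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tkey <- unique(df[, c("year", "month")])
  tkey <- tkey[order(tkey$year, tkey$month), , drop = FALSE]
  nt <- nrow(tkey)
  arr <- array(NA_real_, c(nt, length(lat), length(lon)))
  ti <- match(paste(df$year, df$month), paste(tkey$year, tkey$month))
  arr[cbind(ti, match(df$lat, lat), match(df$lon, lon))] <- df$value
  monthly_grid(arr, tkey$year, tkey$month, lat, lon,
               varname = varname, units = units)
}

#' Write / read a gridded monthly series as NetCDF
#'
#' CF-style axes `lon`, `lat`, `time` (months since the first time step).
#' Requires the `ncdf4` package.
#'
#' @param grid A [monthly_grid()].
#' @param path File path.
#' @param varname,units Variable metadata.
#' @return `read_grid_netcdf` returns a [monthly_grid()].
#' @export
write_grid_netcdf <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF output")
  stopifnot(inherits(grid, "monthly_grid"))
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  tvals <- (grid$year - grid$year[1]) * 12 + (grid$month - grid$month[1])
  dt <- ncdf4::ncdim_def("time",
                         sprintf("months since %d-%02d-15",
                                 grid$year[1], grid$month[1]),
                         tvals, unlim = TRUE)
  var <- ncdf4::ncvar_def(grid$varname, grid$units,
                          list(dlon, dlat, dt), missval = NA_real_)
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(grid$values, c(3, 2, 1)))
  invisible(path)
}

#' @rdname write_grid_netcdf
#' @export
read_grid_netcdf <- function(path, varname = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF input")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(varname)) varname <- names(nc$var)[1]
  v <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  tunit <- nc$dim$time$units
  origin <- as.integer(regmatches(tunit,
    regexec("since (\\d+)-(\\d+)", tunit))[[1]][2:3])
  tvals <- as.numeric(nc$dim$time$vals)
  mo0 <- (origin[2] - 1) + tvals
  year <- origin[1] + mo0 %/% 12
  month <- mo0 %% 12 + 1
  monthly_grid(aperm(v, c(3, 2, 1)), year, month, lat, lon,
               varname = varname,
               units = nc$var[[varname]]$units %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
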