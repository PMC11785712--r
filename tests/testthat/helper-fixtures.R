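# Shared fixtures: small hand-built daily series and random monthly panels.

# A gap-free daily series over given years with constant or function-valued
# fields; defaults satisfy every physical invariant.
make_daily <- function(years = 2001, tx = 20, tn = 10, pp = 0,
                       ss = 6, cc = 0.4, hr = 60) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  n <- length(dates)
  val <- function(v) if (is.function(v)) v(dates) else rep_len(v, n)
  data.frame(date = dates, tx = val(tx), tn = val(tn), pp = val(pp),
             ss = val(ss), cc = val(cc), hr = val(hr))
}

# Random complete monthly panel (year, month, value)
make_monthly_panel <- function(years, sd = 1, trend = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(month = 1:12, year = years)
  data.frame(year = g$year, month = g$month,
             value = trend * g$year + rnorm(nrow(g), 0, sd))
}

# Tiny monthly grid with deterministic values for io/gridded tests
make_grid <- function(ny = 3, nlat = 2, nlon = 3, year0 = 2000,
                      fun = function(t, i, j) t + 10 * i + 100 * j) {
  nt <- ny * 12
  arr <- array(0, c(nt, nlat, nlon))
  for (t in seq_len(nt)) for (i in seq_len(nlat)) for (j in seq_len(nlon))
    arr[t, i, j] <- fun(t, i, j)
  monthly_grid(arr, year = rep(year0 + seq_len(ny) - 1, each = 12),
               month = rep(1:12, ny),
               lat = 42 + seq_len(nlat) * 0.1,
               lon = -3 + seq_len(nlon) * 0.1)
}
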