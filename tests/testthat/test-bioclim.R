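test_that("monthly aggregation reproduces element-wise means and totals", {
  d <- make_daily(2001, tx = 20, tn = 10)
  m <- aggregate_monthly(d)
  expect_equal(nrow(m), 12)
  expect_true(all(m$tx == 20))

  d2 <- make_daily(2001)
  d2$pp[d2$date >= as.Date("2001-06-01") & d2$date <= as.Date("2001-06-10")] <- 1
  m2 <- aggregate_monthly(d2)
  expect_equal(m2$pp_total[m2$month == 6], 10)
  expect_equal(m2$wet_days[m2$month == 6], 0)     # pp = 1 is not > 1 mm

  set.seed(1)
  d3 <- make_daily(2002, tx = function(dd) 15 + rnorm(length(dd)),
                   tn = function(dd) 5 + rnorm(length(dd)),
                   hr = function(dd) runif(length(dd), 40, 90))
  m3 <- aggregate_monthly(d3)
  for (mo in c(2, 7, 12)) {
    sel <- as.integer(format(d3$date, "%m")) == mo
    expect_equal(m3$tx[m3$month == mo], mean(d3$tx[sel]), tolerance = 1e-12)
    expect_equal(m3$hr[m3$month == mo], mean(d3$hr[sel]), tolerance = 1e-12)
  }
})

test_that("partial months are excluded with a warning unless allowed", {
  d <- make_daily(2001)
  d <- d[d$date <= as.Date("2001-11-15"), ]
  expect_warning(m <- aggregate_monthly(d), "partial")
  expect_false(11 %in% m$month)
  expect_true(11 %in% aggregate_monthly(d, allow_partial = TRUE)$month)
})

test_that("day counts use strict thresholds and match a brute-force loop", {
  d <- make_daily(2001, tx = 30.0, tn = 15)
  expect_equal(unname(count_days(d, "HD")), 0L)   # tx = 30 exactly: not hot
  d$tx[100:104] <- 30.5
  expect_equal(unname(count_days(d, "HD")), 5L)

  d2 <- make_daily(2001, pp = 1.0)
  expect_equal(unname(count_days(d2, "WD")), 0L)  # pp = 1 exactly: not wet
  d2$pp[150:156] <- 1.1
  expect_equal(unname(count_days(d2, "WD")), 7L)

  set.seed(2)
  d3 <- make_daily(2003:2004,
                   tx = function(dd) 25 + 8 * rnorm(length(dd)),
                   tn = function(dd) 2 + 3 * rnorm(length(dd)),
                   pp = function(dd) rexp(length(dd)))
  d3$tn <- pmin(d3$tn, d3$tx)
  mo <- as.integer(format(d3$date, "%m")); yr <- format(d3$date, "%Y")
  for (pred in c("HD", "FD", "WD")) {
    got <- count_days(d3, pred)
    hit <- switch(pred, HD = d3$tx > 30, FD = d3$tn < 0, WD = d3$pp > 1)
    brute <- tapply(hit & mo %in% 4:10, yr, sum)
    expect_equal(unname(got), as.integer(unname(brute)))
  }
})

test_that("growing degree days: base case, arithmetic and daily-sum oracle", {
  expect_equal(unname(growing_degree_days(make_daily(2001, tx = 12, tn = 8))), 0)
  # constant Tmean 20 over the 214-day Apr-Oct window
  expect_equal(unname(growing_degree_days(make_daily(2001, tx = 25, tn = 15))),
               2140)
  set.seed(3)
  d <- make_daily(2005, tx = function(dd) 18 + 6 * rnorm(length(dd)))
  d$tn <- d$tx - 8
  sel <- as.integer(format(d$date, "%m")) %in% 4:10
  oracle <- sum(pmax(0, (d$tx[sel] + d$tn[sel]) / 2 - 10))
  expect_equal(unname(growing_degree_days(d)), oracle, tolerance = 1e-9)
  # translation consistency: +1 degC adds exactly (days in window) when
  # Tmean stays above base
  d2 <- make_daily(2001, tx = 25, tn = 15)
  d3 <- d2; d3$tx <- d3$tx + 1; d3$tn <- d3$tn + 1
  expect_equal(unname(growing_degree_days(d3)) -
                 unname(growing_degree_days(d2)), 214)
})

test_that("Huglin index: zero case, closed-form sum, coefficient monotone", {
  expect_equal(unname(huglin_index(make_daily(2001, tx = 10, tn = 10), 42)), 0)
  # Tmean = TX = 20: daily term 10, 183 days, K = 1.03 at 42 deg
  expect_equal(unname(huglin_index(make_daily(2001, tx = 20, tn = 20), 42)),
               10 * 183 * 1.03, tolerance = 1e-9)
  k <- vapply(seq(40, 50, by = 0.5), vinoclim:::huglin_k, numeric(1))
  expect_true(all(diff(k) >= 0))
  expect_error(huglin_index(make_daily(2001), 55), "table")
  expect_error(huglin_index(make_daily(2001), 70), "\\[-60, 60\\]")
})

test_that("Cool Night Index is the September TN mean", {
  expect_equal(unname(cool_night_index(make_daily(2001, tn = 12))), 12)
  d <- make_daily(2001)
  sep <- as.integer(format(d$date, "%m")) == 9
  d$tn[sep] <- rep(c(10, 14), length.out = sum(sep))
  expect_equal(unname(cool_night_index(d)), 12)
  set.seed(4)
  d$tn[sep] <- rnorm(sum(sep), 11, 2)
  expect_equal(unname(cool_night_index(d)), mean(d$tn[sep]))
})

test_that("dryness index: no-flux identity, cap, and a hand-stepped balance", {
  expect_equal(dryness_index(rep(0, 6), rep(0, 6)), 200)

  # huge demand: reserve goes negative but never exceeds the 200 mm cap
  di <- dryness_index(rep(0, 6), rep(300, 6))
  expect_lt(di, 0)
  expect_lte(dryness_index(rep(500, 6), rep(0, 6)), 200)

  # spreadsheet-style oracle, non-leap year, explicit wet-day counts
  p <- c(40, 55, 20, 10, 15, 35)
  pet <- c(60, 90, 130, 150, 120, 80)
  jpm <- c(5, 7, 3, 2, 2, 6)
  N <- c(30, 31, 30, 31, 31, 30)
  k <- c(0.1, 0.3, 0.5, 0.5, 0.5, 0.5)
  W <- 200
  for (m in 1:6) {
    W <- W + p[m] - k[m] * pet[m] -
      (pet[m] / N[m]) * (1 - k[m]) * min(N[m] / 5, jpm[m])
    W <- min(W, 200)
  }
  expect_equal(dryness_index(p, pet, jpm), W, tolerance = 1e-9)
})

test_that("dryness index is monotone in precipitation and demand", {
  p <- c(40, 55, 20, 10, 15, 35); pet <- c(60, 90, 130, 150, 120, 80)
  base <- dryness_index(p, pet)
  expect_gte(dryness_index(p + 10, pet), base)
  expect_lte(dryness_index(p, pet + 10), base)
})

test_that("SPEI window extraction follows the stated month lists", {
  const <- expand.grid(month = 1:12, year = 2000:2002)
  const <- data.frame(year = const$year, month = const$month, value = 1)
  expect_equal(unname(spei_windows(const, 2001)), c(1, 1, 1))

  jan <- const; jan$value <- ifelse(jan$month == 1 & jan$year == 2001, 2.4, 0)
  w <- spei_windows(jan, 2001)
  expect_equal(unname(w["spei3"]), 0)             # Jul-Sep excludes January
  expect_equal(unname(w["spei6"]), 0)             # Mar-Sep excludes January
  expect_equal(unname(w["spei12"]), 2.4 / 12)     # Oct(prev)-Sep includes it

  set.seed(5)
  rnd <- const; rnd$value <- rnorm(nrow(rnd))
  w <- spei_windows(rnd, 2001)
  expect_equal(unname(w["spei3"]),
               mean(rnd$value[rnd$year == 2001 & rnd$month %in% 7:9]))
  expect_equal(unname(w["spei12"]),
               mean(rnd$value[(rnd$year == 2000 & rnd$month %in% 10:12) |
                                (rnd$year == 2001 & rnd$month %in% 1:9)]))
})

test_that("the annual index table assembles all components consistently", {
  w <- generate_daily_weather(weather_gen_config(year_start = 2000,
                                                 year_end = 2004), seed = 6)
  spei <- generate_spei_proxy(w)
  b <- bioclim_table(w, spei = spei)
  expect_equal(b$year, 2000:2004)
  expect_true(all(b$gdd >= 0), all(b$hi >= 0))
  expect_true(all(b$hd >= 0 & b$hd <= 214))
  expect_equal(unname(b$gdd), unname(growing_degree_days(w)))
  expect_equal(unname(b$ci), unname(cool_night_index(w)))
  expect_true(all(is.finite(b$spei3)))
})
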