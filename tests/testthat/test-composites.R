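test_that("per-month detrending removes exact linear trends and is month-local", {
  lin <- make_monthly_panel(2001:2012, sd = 0)
  lin$value <- (0.2 + 0.01 * lin$month) * lin$year   # month-specific lines
  res <- detrend_monthly(lin)
  expect_equal(res$residual, rep(0, nrow(res)), tolerance = 1e-9)

  rnd <- make_monthly_panel(2001:2012, seed = 2)
  r1 <- detrend_monthly(rnd)
  rnd2 <- rnd
  rnd2$value[rnd2$month == 5] <- rnd2$value[rnd2$month == 5] + 7  # shift Mays
  r2 <- detrend_monthly(rnd2)
  expect_equal(r1$residual[r1$month != 5], r2$residual[r2$month != 5])
  expect_equal(r1$residual[r1$month == 5], r2$residual[r2$month == 5],
               tolerance = 1e-9)                     # constant absorbed by trend
})

test_that("detrending matches an explicit per-month least-squares oracle", {
  rnd <- make_monthly_panel(1995:2014, seed = 3)
  res <- detrend_monthly(rnd)
  for (m in c(1, 6, 12)) {
    sub <- rnd[rnd$month == m, ]
    oracle <- residuals(lm(value ~ year, data = sub))
    expect_equal(res$residual[res$month == m], unname(oracle),
                 tolerance = 1e-10)
    expect_equal(mean(res$residual[res$month == m]), 0, tolerance = 1e-9)
  }
})

test_that("tercile classification gives floor(n/3)-sized disjoint extreme sets", {
  set.seed(4)
  tc <- classify_terciles(1993:2017, rnorm(25))
  expect_equal(attr(tc, "m"), 8L)                    # 25 years -> 8 per tercile
  expect_length(attr(tc, "low_years"), 8L)
  expect_length(attr(tc, "high_years"), 8L)
  expect_length(intersect(attr(tc, "low_years"), attr(tc, "high_years")), 0L)

  tc3 <- classify_terciles(2001:2003, c(1, 2, 3), detrend = FALSE)
  expect_equal(attr(tc3, "low_years"), 2001L)
  expect_equal(attr(tc3, "high_years"), 2003L)

  # sort-based oracle on a random 23-year series, no detrending
  x <- rnorm(23); yrs <- 1990:2012
  tc23 <- classify_terciles(yrs, x, detrend = FALSE)
  ord <- order(x)
  expect_setequal(attr(tc23, "low_years"), yrs[ord[1:7]])
  expect_setequal(attr(tc23, "high_years"), yrs[rev(ord)[1:7]])
})

test_that("boundary ties admit the earlier year into the extreme set", {
  yrs <- 2001:2006
  vals <- c(5, 1, 1, 9, 9, 3)                        # ties at both boundaries
  tc <- classify_terciles(yrs, vals, detrend = FALSE)
  expect_equal(attr(tc, "m"), 2L)
  expect_equal(attr(tc, "low_years"), c(2002L, 2003L))
  expect_equal(attr(tc, "high_years"), c(2004L, 2005L))
  vals2 <- c(1, 1, 1, 9, 9, 9)                       # tie straddles boundary
  tc2 <- classify_terciles(yrs, vals2, detrend = FALSE)
  expect_equal(attr(tc2, "low_years"), c(2001L, 2002L))
  expect_equal(attr(tc2, "high_years"), c(2004L, 2005L))
})

test_that("composite anomalies are plain means and vanish over all years", {
  rnd <- make_monthly_panel(2000:2011, seed = 5)
  res <- detrend_monthly(rnd)
  comp <- composite_anomalies(res, c(2001, 2004, 2007))
  for (m in c(2, 8)) {
    expect_equal(comp$composite[comp$month == m],
                 mean(res$residual[res$month == m &
                                     res$year %in% c(2001, 2004, 2007)]))
  }
  all_years <- composite_anomalies(res, 2000:2011)
  expect_equal(all_years$composite, rep(0, 12), tolerance = 1e-9)
})

test_that("bootstrap envelope: degenerate pool, CLT width, reproducibility", {
  zero <- make_monthly_panel(2000:2011, sd = 0)
  zero$value <- 1 * zero$year                        # exact trend, residual 0
  rz <- detrend_monthly(zero)
  env <- bootstrap_envelope(rz, m = 4, n_boot = 500, seed = 1)
  expect_equal(env$lower, rep(0, 12), tolerance = 1e-9)
  expect_equal(env$upper, rep(0, 12), tolerance = 1e-9)

  # i.i.d. N(0,1) residuals, m = 8 of 25 years: half-width ~ 1.645/sqrt(8)
  big <- make_monthly_panel(1993:2017, sd = 1, seed = 6)
  rb <- detrend_monthly(big)
  envb <- bootstrap_envelope(rb, m = 8, n_boot = 4000, seed = 2)
  half <- mean((envb$upper - envb$lower) / 2)
  expect_equal(half, 1.645 / sqrt(8), tolerance = 0.25)

  expect_identical(bootstrap_envelope(rb, 8, 500, seed = 3),
                   bootstrap_envelope(rb, 8, 500, seed = 3))
  expect_error(bootstrap_envelope(rb, m = 30, n_boot = 500, seed = 1,
                                  replace = FALSE), "exceeds")
})

test_that("the envelope widens as the composite sample size shrinks", {
  rb <- detrend_monthly(make_monthly_panel(1993:2017, seed = 7))
  widths <- vapply(c(16, 8, 4), function(m) {
    e <- bootstrap_envelope(rb, m = m, n_boot = 3000, seed = 11)
    mean(e$upper - e$lower)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("null category means land outside the 5-95 envelope ~10% of the time", {
  set.seed(8)
  rb <- detrend_monthly(make_monthly_panel(1993:2017, sd = 1, seed = 9))
  env <- bootstrap_envelope(rb, m = 8, n_boot = 10000, seed = 10)
  years <- 1993:2017
  n_draw <- 1000
  outside <- 0L; total <- 0L
  for (i in seq_len(n_draw)) {
    ys <- sample(years, 8)
    comp <- composite_anomalies(rb, ys)
    outside <- outside + sum(comp$composite < env$lower |
                               comp$composite > env$upper)
    total <- total + nrow(comp)
  }
  expect_equal(outside / total, 0.10, tolerance = 0.30)
})

test_that("full composite report: symmetry, flags, trend invariance", {
  rnd <- make_monthly_panel(1993:2017, seed = 12)
  set.seed(13)
  idx <- data.frame(year = 1993:2017, value = rnorm(25))
  cr <- composite_report(rnd, idx, n_boot = 1000, seed = 14)
  expect_setequal(unique(cr$category), c("high", "low"))
  expect_true(all(cr$lower <= cr$upper))
  expect_equal(cr$significant,
               cr$composite < cr$lower | cr$composite > cr$upper)

  # reversing the index sign swaps high and low composites exactly
  idx_neg <- idx; idx_neg$value <- -idx$value
  cr2 <- composite_report(rnd, idx_neg, n_boot = 1000, seed = 14)
  hi <- cr$composite[cr$category == "high"]
  lo2 <- cr2$composite[cr2$category == "low"]
  expect_equal(hi, lo2)

  # adding a linear-in-year trend to the variable changes nothing
  trended <- rnd; trended$value <- trended$value + 0.7 * trended$year
  cr3 <- composite_report(trended, idx, n_boot = 1000, seed = 14)
  expect_equal(cr$composite, cr3$composite, tolerance = 1e-9)
  expect_equal(cr$lower, cr3$lower, tolerance = 1e-9)
})

test_that("weighted tercile composites balance to zero each month", {
  rnd <- make_monthly_panel(1993:2016, seed = 15)   # n = 24, m = 8
  res <- detrend_monthly(rnd)
  set.seed(16)
  idx <- data.frame(year = 1993:2016, value = rnorm(24))
  tc <- classify_terciles(idx$year, idx$value)
  groups <- split(tc$year, tc$tercile)
  tot <- Reduce(`+`, lapply(groups, function(g)
    length(g) * composite_anomalies(res, g)$composite))
  expect_equal(tot / 24, rep(0, 12), tolerance = 1e-9)
})
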