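# Independent oracles written as plain loops/enumeration; the package
# implementations must match them exactly.

mk_oracle <- function(x) {
  n <- length(x)
  S <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  groups <- table(x)
  tie_term <- 0
  for (t in as.numeric(groups)) if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  varS <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  list(S = S, varS = varS)
}

sen_oracle <- function(x, t) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (t[j] != t[i]) s <- c(s, (x[j] - x[i]) / (t[j] - t[i]))
  median(s)
}

test_that("Mann-Kendall S and tie-corrected variance match the pairwise oracle", {
  expect_equal(mann_kendall(1:10)$S, 45)          # all pairs concordant
  const <- mann_kendall(rep(2, 8))
  expect_equal(const$S, 0)
  expect_equal(const$p_value, 1)

  set.seed(42)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    x <- round(rnorm(n), sample(0:1, 1))          # rounding induces ties
    got <- mann_kendall(x)
    ora <- mk_oracle(x)
    expect_equal(got$S, ora$S)
    expect_equal(got$varS, ora$varS)
    expect_true(abs(got$S) <= n * (n - 1) / 2)
    expect_true(got$p_value >= 0 && got$p_value <= 1)
  }
})

test_that("Mann-Kendall is antisymmetric under reversal and invariant to monotone maps", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(15)
    expect_equal(mann_kendall(x)$S, -mann_kendall(rev(x))$S)
    expect_equal(mann_kendall(x)$S, mann_kendall(exp(x))$S)
  }
})

test_that("Theil-Sen recovers exact lines, resists outliers, matches enumeration", {
  ts <- theil_sen(2 * (1:12) + 1, 1:12)
  expect_equal(ts$slope, 2)
  expect_equal(ts$intercept, 1)
  expect_true(ts$ci[1] <= ts$slope && ts$slope <= ts$ci[2])

  y <- 3 * (1:20) - 4
  y[11] <- 1e6                                    # one gross outlier
  expect_equal(theil_sen(y, 1:20)$slope, 3, tolerance = 1e-9)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    x <- rnorm(n); t <- sort(sample(1:50, n))
    expect_equal(theil_sen(x, t)$slope, sen_oracle(x, t))
  }
})

test_that("Theil-Sen slope is scale-equivariant and skips duplicate times", {
  set.seed(3)
  x <- rnorm(10); t <- 1:10
  expect_equal(theil_sen(5 * x, t)$slope, 5 * theil_sen(x, t)$slope)
  t2 <- c(1, 1, 2:9)                              # a duplicated year
  expect_silent(theil_sen(x, t2))
})

test_that("partial correlation equals the residual-regression construction", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    got <- partial_correlation(x, y, z)
    rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
    expect_equal(got$r_partial, cor(rx, ry), tolerance = 1e-10)
  }
  # uncorrelated-with-control limit: r_partial reduces to plain r
  x <- c(1, 2, 4, 3, 6, 5); y <- c(2, 1, 5, 4, 6, 7)
  z <- c(1, -1, 1, -1, 1, -1) - mean(c(1, -1))
  x <- x - lm(x ~ z)$fitted + mean(x)             # force cor(x, z) = 0
  y <- y - lm(y ~ z)$fitted + mean(y)
  expect_equal(partial_correlation(x, y, z)$r_partial, cor(x, y),
               tolerance = 1e-10)
  expect_error(partial_correlation(z, rnorm(6), z), "degenerate")
})

test_that("Kruskal-Wallis matches hand computation and the stats reference", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7)  # 3.857
  expect_equal(kw$H, 3.857, tolerance = 1e-3)

  expect_equal(kruskal_wallis(list(rep(5, 4), rep(5, 3)))$H, 0)

  set.seed(9)
  for (rep in 1:15) {
    g <- lapply(sample(3:8, 3, replace = TRUE),
                function(n) round(rnorm(n), 1))
    got <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(got$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Conover-Iman flags the dominating group and matches the direct formula", {
  g <- list(a = c(1, 3, 5), b = c(1, 3, 5))
  ci <- conover_iman(g)
  expect_equal(ci$t, 0)
  expect_equal(ci$p_raw, 1)

  sep <- list(lo = c(1, 2, 3, 4), mid = c(10, 11, 12), hi = c(20, 21, 22, 23))
  tab <- conover_iman(sep)
  expect_true(all(tab$significant[tab$group1 == "lo" | tab$group2 == "hi"]))

  # direct formula evaluation on a random 3-group fixture
  set.seed(13)
  g <- lapply(c(5, 6, 4), function(n) round(rnorm(n), 1))
  names(g) <- c("g1", "g2", "g3")
  tab <- conover_iman(g)
  pooled <- unlist(g); r <- rank(pooled)
  N <- length(pooled); k <- 3
  idx <- rep(1:3, lengths(g))
  rbar <- tapply(r, idx, mean)
  H <- kruskal_wallis(g)$H
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  t12 <- (rbar[1] - rbar[2]) /
    sqrt(S2 * (N - 1 - H) / (N - k) * (1 / lengths(g)[1] + 1 / lengths(g)[2]))
  expect_equal(tab$t[tab$group1 == "g1" & tab$group2 == "g2"],
               unname(t12), tolerance = 1e-9)
})

test_that("critical correlation threshold matches closed forms and its limit", {
  expect_equal(round(critical_r(25, 0.05), 2), 0.40)
  expect_equal(critical_r(25, 0.05), 0.396, tolerance = 1e-3)
  expect_equal(critical_r(4, 0.05), qt(0.975, 2) / sqrt(2 + qt(0.975, 2)^2))
  expect_equal(critical_r(4, 0.05), 0.950, tolerance = 1e-3)
  expect_equal(critical_r(1e6), 1.96 / sqrt(1e6), tolerance = 1e-3)
  # agreement with the t-test inversion in cor.test at several n
  for (n in c(10, 25, 60)) {
    r <- critical_r(n)
    x <- rnorm(n)  # p-value at exactly r* must be alpha
    p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    expect_equal(p, 0.05, tolerance = 1e-10)
  }
})

test_that("tests hold their nominal size on Gaussian noise", {
  set.seed(2024)
  n_rep <- 200; n <- 25
  rej_mk <- rej_pc <- rej_kw <- logical(n_rep)
  for (i in 1:n_rep) {
    x <- rnorm(n)
    rej_mk[i] <- mann_kendall(x)$p_value < 0.05
    rej_pc[i] <- partial_correlation(rnorm(n), rnorm(n), rnorm(n))$p_value < 0.05
    rej_kw[i] <- kruskal_wallis(split(x, rep(1:3, length.out = n)))$p_value < 0.05
  }
  expect_gte(mean(rej_mk), 0.02); expect_lte(mean(rej_mk), 0.09)
  expect_gte(mean(rej_pc), 0.02); expect_lte(mean(rej_pc), 0.09)
  expect_gte(mean(rej_kw), 0.02); expect_lte(mean(rej_kw), 0.09)
})
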