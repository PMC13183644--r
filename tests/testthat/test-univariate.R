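# Independent oracles --------------------------------------------------------

# type-7 quantile by direct sort-and-interpolate
interp_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, length(x))] - x[lo + 1])
}

# exact two-sided permutation p for the Mann-Whitney U statistic
exact_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  sets <- combn(length(pool), n1)
  mean(apply(sets, 2, function(idx) abs(u_of(idx) - mu) >= obs - 1e-12))
}

# tie-corrected H computed directly from its definition
hand_kw_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, rep(seq_along(groups), lengths(groups)), sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t <- table(x)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

# exact permutation p for H over all group assignments (small N only)
exact_kw_p <- function(groups) {
  x <- unlist(groups)
  nj <- lengths(groups)
  obs <- hand_kw_h(groups) - 1e-12
  idx_all <- seq_along(x)
  count <- 0; total <- 0
  for (g1 in as.data.frame(combn(idx_all, nj[1]))) {
    rest <- setdiff(idx_all, g1)
    for (g2 in as.data.frame(combn(rest, nj[2]))) {
      g3 <- setdiff(rest, g2)
      h <- hand_kw_h(list(x[g1], x[g2], x[g3]))
      count <- count + (h >= obs); total <- total + 1
    }
  }
  count / total
}

# ----------------------------------------------------------------------------

test_that("group summaries match the sort-and-interpolate quantile oracle", {
  s <- group_summary(c(1, 2, 3, 4, 5), rep("all", 5))
  expect_equal(s[, c("median", "p25", "p75")],
               data.frame(median = 3, p25 = 2, p75 = 4))
  expect_equal(s$percent, 100)

  two <- group_summary(rep(c(10, 20, 30), 2), rep(c("a", "b"), each = 3))
  expect_equal(two$percent, c(50, 50))
  expect_equal(two$median, c(20, 20))

  set.seed(31)
  v <- rlnorm(97)
  g <- sample(c("p", "q"), 97, replace = TRUE)
  s <- group_summary(v, g)
  for (i in seq_len(nrow(s))) {
    vv <- v[g == s$level[i]]
    expect_equal(s$p25[i], interp_quantile(vv, 0.25))
    expect_equal(s$median[i], interp_quantile(vv, 0.5))
    expect_equal(s$p75[i], interp_quantile(vv, 0.75))
  }
  expect_error(group_summary(numeric(0), character(0)), class = "domain_error")
})

test_that("Mann-Whitney is null on exchangeable samples and flags degeneracy", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  d <- mann_whitney(rep(5, 4), rep(5, 6))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
})

test_that("Mann-Whitney normal p tracks the exact permutation p near alpha", {
  # separated samples: the screen's accept/reject decision happens in this
  # tail, where the no-continuity normal approximation is accurate; in the
  # middle of the null distribution it can be off by > 0.1 and is not relied on
  cases <- list(list(x = c(1.2, 3.4, 2.2, 5.1), y = c(4.0, 6.2, 7.1, 5.5)),
                list(x = c(1, 2, 3, 4), y = c(5, 6, 7, 8)),
                list(x = c(0.3, 0.8, 1.4, 2.9), y = c(2.2, 3.1, 4.0, 5.6)))
  for (cs in cases) {
    approx <- mann_whitney(cs$x, cs$y)$p_value
    exact <- exact_mw_p(cs$x, cs$y)
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("the tie-corrected variance matches its explicit formula", {
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 3, 3, 4)
  n1 <- 5; n2 <- 4; N <- 9
  t <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  r <- mann_whitney(x, y)
  U <- sum(rank(c(x, y))[1:5]) - n1 * (n1 + 1) / 2
  expect_equal(r$statistic, (U - n1 * n2 / 2) / sqrt(sigma2))
  # and the p agrees with the standard package computation
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(r$p_value, wt$p.value)
})

test_that("Mann-Whitney Z is negative when the first sample ranks low", {
  lo_first <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_lt(lo_first$statistic, 0)
  expect_gt(mann_whitney(c(10, 11, 12), c(1, 2, 3))$statistic, 0)
})

test_that("Kruskal-Wallis agrees with the hand formula and permutation oracle", {
  tied <- list(c(3, 1, 4), c(1, 5, 9), c(2, 6, 5))
  r_tied <- kruskal_wallis(tied)
  expect_equal(r_tied$statistic, hand_kw_h(tied), tolerance = 1e-12)
  expect_equal(r_tied$df, 2)
  # permutation comparison in the tail, where the screen decides
  groups <- list(c(1, 2, 4), c(3, 5, 6), c(7, 8, 9))
  r <- kruskal_wallis(groups)
  expect_equal(r$statistic, hand_kw_h(groups), tolerance = 1e-12)
  expect_lt(abs(r$p_value - exact_kw_p(groups)), 0.03)

  ident <- kruskal_wallis(list(c(1, 2), c(1, 2), c(2, 1)))
  expect_equal(ident$statistic, 0)
  all_same <- kruskal_wallis(list(rep(7, 3), rep(7, 3), rep(7, 2)))
  expect_true(all_same$degenerate)
  expect_equal(all_same$p_value, 1)
})

test_that("merging two identical groups leaves the rank sums consistent", {
  g <- list(c(1, 4, 6), c(2, 2, 8), c(2, 2, 8), c(9, 3, 5))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, hand_kw_h(g), tolerance = 1e-12)
})

test_that("rank tests are invariant to monotone transforms of the outcome", {
  set.seed(17)
  x <- rlnorm(60); y <- rlnorm(45, meanlog = 0.4)
  raw <- mann_whitney(x, y)
  logd <- mann_whitney(log(x), log(y))
  expect_equal(raw$statistic, logd$statistic)
  expect_equal(raw$p_value, logd$p_value)

  g <- split(rlnorm(90), rep(1:3, 30))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, log))$statistic)
})

test_that("the screen selects by p < alpha and honours the boundary alpha = 1", {
  set.seed(23)
  n <- 400
  d <- data.frame(
    x4_sex = sample(1:2, n, TRUE),
    x9_los_group = sample(1:4, n, TRUE),
    y1_log_total = rnorm(n))
  d$y1_log_total <- d$y1_log_total + 0.8 * d$x9_los_group   # strong LOS effect

  scr <- univariate_screen(d, c("x4_sex", "x9_los_group"), "y1_log_total", alpha = 0.05)
  expect_true("x9_los_group" %in% scr$selected)
  expect_equal(scr$results$x9_los_group$statistic_kind, "H")
  expect_equal(scr$results$x4_sex$statistic_kind, "Z")

  all_in <- univariate_screen(d, c("x4_sex", "x9_los_group"), "y1_log_total",
                              alpha = 1)
  expect_setequal(all_in$selected, c("x4_sex", "x9_los_group"))

  d$x_const <- 1
  expect_warning(
    scr2 <- univariate_screen(d, c("x_const", "x4_sex"), "y1_log_total"),
    "single observed level")
  expect_false("x_const" %in% names(scr2$results))
})

test_that("screen tables flatten to one row per level", {
  set.seed(29)
  d <- data.frame(x4_sex = sample(1:2, 100, TRUE),
                  x2_insurance = sample(1:3, 100, TRUE),
                  y1_log_total = rnorm(100))
  tab <- screen_table(univariate_screen(d, c("x4_sex", "x2_insurance")))
  expect_equal(nrow(tab), 5)
  expect_equal(sum(!is.na(tab$p_value)), 2)
  expect_equal(sum(tab$percent[tab$variable == "x2_insurance"]), 100)
})
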