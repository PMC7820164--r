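test_that("pair correlation calibrates to 1 on CSR", {
  withr::local_seed(21)
  means <- vapply(1:20, function(k) {
    m <- csr_map(rpois(1, 400))
    g <- pair_correlation(m)
    mean(g$value[g$r >= 2])
  }, numeric(1))
  expect_equal(mean(means), 1, tolerance = 0.05)
})

test_that("rings with no pairs report zero", {
  # 10 m square lattice: nothing closer than 10 m
  xy <- expand.grid(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  m <- toy_map(xy$x, xy$y)
  g <- pair_correlation(m, r_max = 15)
  expect_true(all(g$value[g$r < 9.5] == 0))
  expect_gt(g$value[g$r == 10.5], 0)
})

test_that("two-point map matches the hand-evaluated estimator", {
  # points (30,40) and (33,44): distance 5, |dx| = 3, |dy| = 4,
  # window 100 x 100. Ordered-pair sum = 2 / ((100-3)(100-4)); the 5 m
  # distance falls in the [5,6) annulus (center 5.5).
  m <- toy_map(c(30, 33), c(40, 44))
  g <- pair_correlation(m, r_max = 15)
  lam <- 2 / 1e4
  ring_area <- pi * (6^2 - 5^2)
  expected <- (2 / ((100 - 3) * (100 - 4))) / (lam^2 * ring_area)
  expect_equal(g$value[g$r == 5.5], expected, tolerance = 1e-12)
  expect_true(all(g$value[g$r != 5.5] == 0))
})

test_that("bivariate pcf reduces to univariate and handles toys", {
  withr::local_seed(5)
  m <- csr_map(100)
  all_pts <- rep(TRUE, 100)
  g1 <- pair_correlation(m)
  g12 <- bivariate_pair_correlation(m, all_pts, all_pts)
  expect_identical(g12$value, g1$value)

  # one point per type at distance 5: only the ordered (1,2) pair counts
  m2 <- toy_map(c(30, 33), c(40, 44))
  g_ab <- bivariate_pair_correlation(m2, c(TRUE, FALSE), c(FALSE, TRUE))
  lam1 <- 1 / 1e4
  expected <- (1 / ((100 - 3) * (100 - 4))) / (lam1^2 * pi * 11)
  expect_equal(g_ab$value[g_ab$r == 5.5], expected)

  expect_error(bivariate_pair_correlation(m2, c(FALSE, FALSE), c(TRUE, TRUE)),
               "non-empty")
})

test_that("independent superposed patterns give bivariate g near 1", {
  withr::local_seed(31)
  vals <- vapply(1:15, function(k) {
    n1 <- 150; n2 <- 150
    m <- toy_map(runif(n1 + n2, 0, 100), runif(n1 + n2, 0, 100))
    g <- bivariate_pair_correlation(m, c(rep(TRUE, n1), rep(FALSE, n2)),
                                    c(rep(FALSE, n1), rep(TRUE, n2)))
    mean(g$value[g$r >= 2])
  }, numeric(1))
  expect_equal(mean(vals), 1, tolerance = 0.05)
})

test_that("all estimators agree exactly with naive O(n^2) loops", {
  withr::local_seed(41)
  breaks <- seq(0, 15, by = 1)
  for (rep in 1:8) {
    n <- sample(20:120, 1)
    m <- toy_map(runif(n, 0, 60), runif(n, 0, 60),
                 dbh = rlnorm(n, log(25), 0.5), width = 60,
                 status = sample(c("alive", "killed"), n, replace = TRUE,
                                 prob = c(0.6, 0.4)))
    if (length(unique(m$status)) < 2) next
    oracle <- naive_stats(m, breaks, dead = m$status == "killed")

    expect_equal(pair_correlation(m, breaks = breaks)$value, oracle$g,
                 tolerance = 1e-12)
    expect_equal(r_mark_correlation(m, breaks = breaks)$value,
                 oracle$k_mark, tolerance = 1e-12)
    expect_equal(mark_variogram(m, breaks = breaks)$value, oracle$gamma,
                 tolerance = 1e-12)
    md <- mortality_difference_statistics(m, breaks = breaks)
    expect_equal(md$g_cluster$value, oracle$g_cluster, tolerance = 1e-12)
    expect_equal(md$g_densdep$value, oracle$g_densdep, tolerance = 1e-12)

    dead <- m$status == "killed"
    expect_equal(
      bivariate_pair_correlation(m, dead, !dead, breaks = breaks)$value,
      naive_bivariate(m, dead, !dead, breaks), tolerance = 1e-12)
  }
})

test_that("pair statistics are order- and translation-invariant", {
  withr::local_seed(17)
  n <- 80
  df <- data.frame(id = 1:n, x = runif(n, 0, 70), y = runif(n, 0, 70),
                   species = "P", dbh = rlnorm(n, 3, 0.4))
  m <- stem_map(df, plot_window(0, 70, 0, 70))
  g <- pair_correlation(m)
  perm <- sample(n)
  g_p <- pair_correlation(stem_map(df[perm, ], plot_window(0, 70, 0, 70)))
  expect_equal(g_p$value, g$value, tolerance = 1e-12)
  df2 <- transform(df, x = x + 500, y = y - 300)
  g_t <- pair_correlation(stem_map(df2, plot_window(500, 570, -300, -230)))
  expect_equal(g_t$value, g$value, tolerance = 1e-12)
})

test_that("mortality statistics are centred on zero under coin-flip labels", {
  withr::local_seed(13)
  m <- csr_map(200)
  sums <- matrix(0, nrow = 15, ncol = 2)
  n_draws <- 80
  for (k in seq_len(n_draws)) {
    mm <- restamp_with(m, status = sample(c("alive", "killed"), 200,
                                          replace = TRUE))
    if (length(unique(mm$status)) < 2) next
    md <- mortality_difference_statistics(mm)
    sums[, 1] <- sums[, 1] + md$g_cluster$value
    sums[, 2] <- sums[, 2] + md$g_densdep$value
  }
  means <- sums / n_draws
  expect_lt(max(abs(means[3:15, ])), 0.15)
  expect_lt(abs(mean(means)), 0.05)
})

test_that("a killed clump yields positive clustering of mortality", {
  withr::local_seed(19)
  # dead trees in a tight 8 m clump, alive trees spread across the window
  nd <- 25; na_ <- 75
  m <- toy_map(c(runif(nd, 46, 54), runif(na_, 0, 100)),
               c(runif(nd, 46, 54), runif(na_, 0, 100)),
               status = c(rep("killed", nd), rep("alive", na_)))
  md <- mortality_difference_statistics(m)
  expect_gt(mean(md$g_cluster$value[md$g_cluster$r <= 5]), 0)
  oracle <- naive_stats(m, seq(0, 15, 1), dead = m$status == "killed")
  expect_equal(md$g_cluster$value, oracle$g_cluster, tolerance = 1e-12)
})

test_that("density-dependent labeling yields positive g_densdep", {
  withr::local_seed(23)
  m <- csr_map(250)
  # kill where the 5 m neighbor count is above the median
  cnt <- vapply(seq_len(250), function(i) {
    sum((m$x - m$x[i])^2 + (m$y - m$y[i])^2 <= 25) - 1
  }, numeric(1))
  status <- ifelse(cnt > median(cnt), "killed", "alive")
  md <- mortality_difference_statistics(restamp_with(m, status = status))
  expect_gt(mean(md$g_densdep$value[md$g_densdep$r <= 5]), 0)
})

test_that("r-mark correlation reproduces hand-computed pair means", {
  # constant marks: every defined ring reports the constant
  k_const <- r_mark_correlation(toy_map(c(10, 20, 30), rep(10, 3), dbh = 30))
  expect_true(all(k_const$value[!is.na(k_const$value)] == 30))
  expect_equal(k_const$value[k_const$r == 10.5], 30) # 10 m pairs, bin [10,11)

  # collinear points at x = 0, 3, 7 (marks 10, 20, 40): pair distances
  # 3 (10,20), 4 (20,40), 7 (10,40)
  m <- toy_map(c(10, 13, 17), rep(50, 3), dbh = c(10, 20, 40))
  k <- r_mark_correlation(m)
  expect_equal(k$value[k$r == 3.5], 15) # pair (10,20), both directions
  expect_equal(k$value[k$r == 4.5], 30) # pair (20,40)
  expect_equal(k$value[k$r == 7.5], 25) # pair (10,40)
  expect_true(all(is.na(k$value[!k$r %in% c(3.5, 4.5, 7.5)])))
  expect_equal(attr(k, "mark_mean"), mean(c(10, 20, 40)))
})

test_that("mark variogram matches hand-computed semivariances", {
  m <- toy_map(c(10, 13, 17), rep(50, 3), dbh = c(10, 20, 40))
  v <- mark_variogram(m, normalized = FALSE)
  expect_equal(v$value[v$r == 3.5], 50)   # 0.5*(10-20)^2
  expect_equal(v$value[v$r == 4.5], 200)  # 0.5*(20-40)^2
  expect_equal(v$value[v$r == 7.5], 450)  # 0.5*(10-40)^2

  vn <- mark_variogram(m)
  expect_equal(vn$value[vn$r == 3.5], 50 / var(c(10, 20, 40)))

  const <- toy_map(c(10, 13, 17), rep(50, 3), dbh = 25)
  expect_true(all(mark_variogram(const, normalized = FALSE)$value %in%
                    c(0, NA)))
  expect_error(mark_variogram(const), "variance")
})

test_that("shuffled marks give a variogram near 1 and k near the mean", {
  withr::local_seed(29)
  m <- csr_map(150)
  marks <- rlnorm(150, log(30), 0.5)
  v_means <- k_means <- numeric(40)
  for (i in 1:40) {
    mm <- restamp_with(m, dbh = sample(marks))
    v_means[i] <- mean(mark_variogram(mm)$value, na.rm = TRUE)
    k_means[i] <- mean(r_mark_correlation(mm)$value, na.rm = TRUE)
  }
  expect_equal(mean(v_means), 1, tolerance = 0.03)
  expect_equal(mean(k_means), mean(marks), tolerance = 0.03 * mean(marks))
})
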