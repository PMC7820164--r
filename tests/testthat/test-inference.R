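test_that("random labeling conserves statuses and locations", {
  withr::local_seed(9)
  m <- csr_map(60)
  m <- restamp_with(m, status = c(rep("killed", 20), rep("alive", 40)))
  sims <- simulate_null(m, null_spec("random_label", n_sim = 39, seed = 4))
  expect_length(sims, 39)
  for (s in sims[1:5]) {
    expect_equal(sort(table(s$status)), sort(table(m$status)))
    expect_equal(s$x, m$x)
    expect_equal(s$y, m$y)
  }
  expect_false(all(sims[[1]]$status == m$status))
})

test_that("random marking permutes the dbh multiset over fixed points", {
  withr::local_seed(10)
  m <- csr_map(50)
  m <- restamp_with(m, dbh = rlnorm(50, 3, 0.5))
  sims <- simulate_null(m, null_spec("random_mark", n_sim = 39, seed = 2))
  expect_equal(sort(sims[[1]]$dbh), sort(m$dbh))
  expect_equal(sims[[1]]$x, m$x)
})

test_that("conditioned inhomogeneous Poisson draws preserve n and track lambda", {
  withr::local_seed(12)
  # strongly bimodal pattern: most mass in the left half
  n_left <- 180; n_right <- 20
  m <- toy_map(c(runif(n_left, 0, 40), runif(n_right, 60, 100)),
               runif(200, 0, 100))
  sims <- simulate_null(m, null_spec("inhom_poisson", n_sim = 60, seed = 8,
                                     bandwidth = 20))
  expect_true(all(vapply(sims, nrow, integer(1)) == 200))
  expect_true(all(vapply(sims, function(s) {
    all(in_window_vec(s, map_window(m)))
  }, logical(1))))
  # mass ratio between window halves matches the intensity field's
  f <- estimate_intensity(m, 20, 1)
  mass <- f$z * outer(f$xw, f$yw)
  lam_ratio <- sum(mass[f$xc < 50, ]) / sum(mass)
  frac_left <- mean(vapply(sims, function(s) mean(s$x < 50), numeric(1)))
  expect_equal(frac_left, lam_ratio, tolerance = 0.02)
})

test_that("unconditioned draws vary their counts around the integral", {
  withr::local_seed(14)
  m <- csr_map(100)
  sims <- simulate_null(m, null_spec("inhom_poisson", n_sim = 60, seed = 3,
                                     condition_on_n = FALSE))
  counts <- vapply(sims, nrow, integer(1))
  expect_gt(sd(counts), 0)
  expect_equal(mean(counts), 100, tolerance = 0.1)
})

test_that("global envelope degenerates correctly when empirical equals the null mean", {
  withr::local_seed(15)
  r <- seq(0.5, 14.5, by = 1)
  nulls <- lapply(1:99, function(k) {
    f <- tibble::tibble(r = r, value = rnorm(15, 1, 0.1))
    class(f) <- c("fcf", class(f)); f
  })
  null_mat <- vapply(nulls, function(f) f$value, numeric(15))
  emp <- tibble::tibble(r = r, value = rowMeans(null_mat))
  class(emp) <- c("fcf", class(emp))
  env <- global_envelope(emp, nulls)
  expect_true(all(abs(env$z) < 1e-12))
  expect_false(attr(env, "significant"))
  expect_equal(attr(env, "r_averaged_z"), 0)
})

test_that("a single large excursion triggers global significance", {
  withr::local_seed(16)
  r <- seq(0.5, 14.5, by = 1)
  nulls <- lapply(1:99, function(k) {
    f <- tibble::tibble(r = r, value = rnorm(15, 0, 0.05))
    class(f) <- c("fcf", class(f)); f
  })
  null_mat <- vapply(nulls, function(f) f$value, numeric(15))
  crit_scale <- max(apply(abs(scale(t(null_mat))), 1, max))
  vals <- rowMeans(null_mat)
  vals[8] <- vals[8] + 2 * crit_scale * sd(null_mat[8, ])
  emp <- tibble::tibble(r = r, value = vals)
  class(emp) <- c("fcf", class(emp))
  env <- global_envelope(emp, nulls)
  expect_true(attr(env, "significant"))
  expect_true(env$observed[8] > env$hi[8])
})

test_that("the critical value follows the (n_sim + 1)(1 - alpha) convention", {
  withr::local_seed(18)
  r <- seq(0.5, 4.5, by = 1)
  nulls <- lapply(1:99, function(k) {
    f <- tibble::tibble(r = r, value = rnorm(5))
    class(f) <- c("fcf", class(f)); f
  })
  emp <- tibble::tibble(r = r, value = rnorm(5))
  class(emp) <- c("fcf", class(emp))
  env <- global_envelope(emp, nulls, alpha = 0.05)
  pool <- cbind(emp$value, vapply(nulls, function(f) f$value, numeric(5)))
  m <- rowMeans(pool); s <- apply(pool, 1, sd)
  M <- apply(abs((pool - m) / s), 2, max)
  expect_equal(attr(env, "crit"), sort(M)[95]) # ceiling((99 + 1) * 0.95)
})

test_that("lowering alpha never creates significance, and global is conservative", {
  withr::local_seed(20)
  r <- seq(0.5, 14.5, by = 1)
  for (rep in 1:20) {
    null_mat <- matrix(rnorm(15 * 59), nrow = 15)
    nulls <- lapply(seq_len(59), function(k) {
      f <- tibble::tibble(r = r, value = null_mat[, k])
      class(f) <- c("fcf", class(f)); f
    })
    emp <- tibble::tibble(r = r, value = rnorm(15, 0, 1.4))
    class(emp) <- c("fcf", class(emp))
    e05 <- global_envelope(emp, nulls, alpha = 0.05)
    e01 <- global_envelope(emp, nulls, alpha = 0.01)
    if (!attr(e05, "significant")) expect_false(attr(e01, "significant"))

    # pointwise 2.5/97.5 banding implies inside the global band
    lo_pw <- apply(null_mat, 1, quantile, 0.025)
    hi_pw <- apply(null_mat, 1, quantile, 0.975)
    if (all(emp$value >= lo_pw & emp$value <= hi_pw)) {
      expect_false(attr(e05, "significant"))
    }
  }
})

test_that("degenerate zero-variance bins warn and score z = 0", {
  withr::local_seed(19)
  r <- seq(0.5, 4.5, by = 1)
  nulls <- lapply(1:39, function(k) {
    f <- tibble::tibble(r = r, value = c(1, rnorm(4)))
    class(f) <- c("fcf", class(f)); f
  })
  # empirical also constant at the first bin: the pooled sd is zero there
  emp <- tibble::tibble(r = r, value = c(1, rnorm(4)))
  class(emp) <- c("fcf", class(emp))
  expect_warning(env <- global_envelope(emp, nulls), "zero null variance")
  expect_equal(env$z[1], 0)

  # constant nulls with a deviating empirical are not degenerate: the
  # pooled sd is positive and the bin scores a large positive z
  emp2 <- tibble::tibble(r = r, value = c(5, rnorm(4)))
  class(emp2) <- c("fcf", class(emp2))
  env2 <- global_envelope(emp2, nulls)
  expect_gt(env2$z[1], 3)
})

test_that("envelope_test wires statistics to their null models", {
  withr::local_seed(22)
  m <- csr_map(120)
  m <- restamp_with(m, dbh = rlnorm(120, log(30), 0.4),
                    status = sample(c("alive", "killed"), 120, replace = TRUE))
  env_g <- envelope_test(m, "g", n_sim = 49, seed = 1)
  expect_s3_class(env_g, "fs_envelope")
  expect_equal(attr(env_g, "n_sim"), 49)

  env_k <- envelope_test(m, "k_mark", n_sim = 49, seed = 2)
  expect_equal(attr(env_k, "kind"), "k_mark")
  # CSR with independent marks: no departure expected in the vast majority
  # of runs; at least check the machinery returns finite summaries
  expect_true(is.finite(attr(env_k, "r_averaged_z")))

  both <- suppressWarnings(mortality_envelopes(m, n_sim = 49, seed = 3))
  expect_named(both, c("g_cluster", "g_densdep"))
  expect_s3_class(both$g_cluster, "fs_envelope")

  # same seed, same result (determinism of the null batch)
  env_g2 <- envelope_test(m, "g", n_sim = 49, seed = 1)
  expect_equal(env_g$lo, env_g2$lo, tolerance = 1e-12)
})
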