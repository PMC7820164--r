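# Fixture builders and independent brute-force oracles. The oracles use
# explicit double loops and re-derive every formula inline so they share no
# code with the package implementation.

csr_map <- function(n, width = 100, height = width, dbh = 10) {
  stem_map(
    data.frame(id = seq_len(n),
               x = runif(n, 0, width), y = runif(n, 0, height),
               species = "X", dbh = dbh),
    plot_window(0, width, 0, height)
  )
}

toy_map <- function(x, y, dbh = 10, width = 100, height = width,
                    status = NULL, species = "X") {
  df <- data.frame(id = seq_along(x), x = x, y = y, species = species,
                   dbh = dbh)
  if (!is.null(status)) df$status <- status
  stem_map(df, plot_window(0, width, 0, height))
}

in_window_vec <- function(map, w) {
  map$x >= w$x_min & map$x <= w$x_max & map$y >= w$y_min & map$y <= w$y_max
}

restamp_with <- function(map, ...) {
  df <- as.data.frame(map)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  stem_map(df, map_window(map), map_label(map))
}

restamp_with_rows <- function(map, rows) {
  stem_map(as.data.frame(map)[rows, ], map_window(map), map_label(map))
}

# Ring index of a distance under the package's binning convention:
# left-closed right-open bins, last bin closed. Returns 0 outside.
naive_ring <- function(d, breaks) {
  nb <- length(breaks) - 1
  for (k in seq_len(nb)) {
    hi_ok <- if (k == nb) d <= breaks[k + 1] else d < breaks[k + 1]
    if (d >= breaks[k] && hi_ok && d > 0) return(k)
  }
  0L
}

# All second-order and mark statistics from explicit O(n^2) loops.
# `dead` may be NULL (then only g/k/gamma are computed).
naive_stats <- function(map, breaks, dead = NULL) {
  w <- map_window(map)
  a <- w$x_max - w$x_min; b <- w$y_max - w$y_min
  A <- a * b
  n <- nrow(map)
  nb <- length(breaks) - 1
  ring_area <- pi * (breaks[-1]^2 - breaks[-(nb + 1)]^2)
  m <- map$dbh

  g_num <- numeric(nb)
  k_sum <- numeric(nb); k_cnt <- numeric(nb)
  v_sum <- numeric(nb)
  dd <- ad <- dall <- aall <- numeric(nb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(map$x[i] - map$x[j]); dy <- abs(map$y[i] - map$y[j])
      d <- sqrt(dx^2 + dy^2)
      k <- naive_ring(d, breaks)
      if (k == 0) next
      wt <- 1 / ((a - dx) * (b - dy))
      g_num[k] <- g_num[k] + wt
      k_sum[k] <- k_sum[k] + m[j]; k_cnt[k] <- k_cnt[k] + 1
      v_sum[k] <- v_sum[k] + 0.5 * (m[i] - m[j])^2
      if (!is.null(dead)) {
        if (dead[i] && dead[j]) dd[k] <- dd[k] + wt
        if (!dead[i] && dead[j]) ad[k] <- ad[k] + wt
        if (dead[i]) dall[k] <- dall[k] + wt
        if (!dead[i]) aall[k] <- aall[k] + wt
      }
    }
  }
  lam <- n / A
  out <- list(
    g = g_num / (lam^2 * ring_area),
    k_mark = ifelse(k_cnt > 0, k_sum / k_cnt, NA_real_),
    gamma = ifelse(k_cnt > 0, v_sum / k_cnt, NA_real_) / var(m)
  )
  if (!is.null(dead)) {
    n_d <- sum(dead); n_a <- n - n_d
    lam_d <- n_d / A; lam_a <- n_a / A
    g_dd <- dd / (lam_d^2 * ring_area)
    g_ad <- ad / (lam_a * lam_d * ring_area)
    g_dall <- dall / (lam_d * lam * ring_area)
    g_aall <- aall / (lam_a * lam * ring_area)
    out$g_cluster <- g_dd - g_ad
    out$g_densdep <- g_dall - g_aall
  }
  out
}

# Bivariate pair correlation by explicit loops over ordered pairs.
naive_bivariate <- function(map, in1, in2, breaks) {
  w <- map_window(map)
  a <- w$x_max - w$x_min; b <- w$y_max - w$y_min
  A <- a * b
  nb <- length(breaks) - 1
  ring_area <- pi * (breaks[-1]^2 - breaks[-(nb + 1)]^2)
  num <- numeric(nb)
  for (i in which(in1)) {
    for (j in which(in2)) {
      if (i == j) next
      dx <- abs(map$x[i] - map$x[j]); dy <- abs(map$y[i] - map$y[j])
      k <- naive_ring(sqrt(dx^2 + dy^2), breaks)
      if (k == 0) next
      num[k] <- num[k] + 1 / ((a - dx) * (b - dy))
    }
  }
  num / ((sum(in1) / A) * (sum(in2) / A) * ring_area)
}

# Group partition by transitive closure over the full distance matrix
# (Floyd-Warshall style boolean closure).
naive_groups <- function(x, y, linkage) {
  n <- length(x)
  adj <- outer(x, x, "-")^2 + outer(y, y, "-")^2 <= linkage^2
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  membership <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      g <- g + 1L
      membership[adj[i, ]] <- g
    }
  }
  membership
}

# Canonical form of a partition for comparison across labelings.
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# Profile log-likelihood oracle for the common-CV model, maximized on a
# dense grid of (tau, mu_1, mu_2) by nested 1-D grid refinement.
naive_cv_slrt <- function(a, b) {
  samples <- list(a, b)
  loglik <- function(x, mu, sig) sum(dnorm(x, mu, sig, log = TRUE))
  best_mu <- function(x, tau) {
    f <- function(mu) loglik(x, mu, tau * mu)
    grid <- seq(mean(x) * 0.2, mean(x) * 3, length.out = 400)
    mu0 <- grid[which.max(vapply(grid, f, numeric(1)))]
    opt <- optimize(f, c(mu0 * 0.8, mu0 * 1.25), maximum = TRUE, tol = 1e-10)
    opt$objective
  }
  l_unres <- sum(vapply(samples, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    loglik(x, mean(x), s)
  }, numeric(1)))
  prof <- function(tau) sum(vapply(samples, best_mu, numeric(1), tau = tau))
  taus <- exp(seq(log(0.01), log(5), length.out = 300))
  t0 <- taus[which.max(vapply(taus, prof, numeric(1)))]
  opt <- optimize(prof, c(t0 * 0.7, t0 * 1.4), maximum = TRUE, tol = 1e-10)
  dev <- max(0, 2 * (l_unres - opt$objective))
  cv <- vapply(samples, function(x) sqrt(mean((x - mean(x))^2)) / mean(x),
               numeric(1))
  list(statistic = sign(cv[1] - cv[2]) * sqrt(dev), deviance = dev,
       p.value = 2 * pnorm(-sqrt(dev)))
}
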