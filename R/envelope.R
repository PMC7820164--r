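#' Null-model specification for Monte Carlo inference
#'
#' Three permutation/simulation nulls drive the envelope tests:
#' * `"inhom_poisson"`: points redistributed by an inhomogeneous Poisson
#'   process whose intensity is the Epanechnikov kernel estimate of the
#'   observed pattern (bandwidth 20 m, resolution 1 m by default). By
#'   default draws are conditioned on the observed point count so the test
#'   isolates second-order structure.
#' * `"random_label"`: alive/killed statuses permuted over fixed locations
#'   (mortality is conditioned on the prefire pattern, so points never
#'   move).
#' * `"random_mark"`: quantitative marks (dbh) permuted over fixed
#'   locations.
#'
#' @param kind One of `"inhom_poisson"`, `"random_label"`, `"random_mark"`.
#' @param n_sim Number of simulations (default 399; must be >= 39).
#' @param seed Integer seed for the simulation batch.
#' @param bandwidth,resolution Intensity-estimation parameters
#'   (`inhom_poisson` only).
#' @param condition_on_n Condition `inhom_poisson` draws on the observed
#'   count (default `TRUE`); `FALSE` draws Poisson counts.
#' @return A `null_spec` list.
#' @export
null_spec <- function(kind = c("inhom_poisson", "random_label", "random_mark"),
                      n_sim = 399, seed = NULL, bandwidth = 20,
                      resolution = 1, condition_on_n = TRUE) {
  kind <- match.arg(kind)
  assert_number(n_sim, "n_sim", lower = 39)
  structure(
    list(kind = kind, n_sim = as.integer(n_sim), seed = seed,
         bandwidth = bandwidth, resolution = resolution,
         condition_on_n = condition_on_n),
    class = "null_spec"
  )
}

#' Simulate realizations of a null model
#'
#' @param map A [stem_map()]; for `"random_label"` it must carry both
#'   alive and killed statuses.
#' @param spec A [null_spec()].
#' @return A list of `spec$n_sim` stem maps.
#' @export
simulate_null <- function(map, spec) {
  stopifnot(inherits(spec, "null_spec"))
  with_seed(spec$seed, {
    switch(spec$kind,
      random_label = {
        require_both_statuses(map)
        lapply(seq_len(spec$n_sim), function(k) {
          restamp(dplyr::mutate(as_tibble(map), status = sample(.data$status)),
                  map)
        })
      },
      random_mark = {
        lapply(seq_len(spec$n_sim), function(k) {
          restamp(dplyr::mutate(as_tibble(map), dbh = sample(.data$dbh)), map)
        })
      },
      inhom_poisson = {
        field <- estimate_intensity(map, spec$bandwidth, spec$resolution)
        lapply(seq_len(spec$n_sim), function(k) {
          n_k <- if (spec$condition_on_n) nrow(map) else
            rpois(1, intensity_integral(field))
          draw_inhom_points(field, n_k, map)
        })
      }
    )
  })
}

# Sample n points with density proportional to a gridded intensity:
# choose cells by their intensity mass, jitter uniformly within the cell.
draw_inhom_points <- function(field, n, template) {
  mass <- as.vector(field$z * outer(field$xw, field$yw))
  cells <- sample.int(length(mass), n, replace = TRUE, prob = mass)
  nx <- length(field$xc)
  cx <- ((cells - 1L) %% nx) + 1L
  cy <- ((cells - 1L) %/% nx) + 1L
  trees <- tibble(
    id = sprintf("s%05d", seq_len(n)),
    x = field$xc[cx] + runif(n, -0.5, 0.5) * field$xw[cx],
    y = field$yc[cy] + runif(n, -0.5, 0.5) * field$yw[cy],
    species = "SIM", dbh = 1
  )
  new_stem_map(trees, field$window, label = map_label(template))
}

#' Studentized global envelope test
#'
#' Implements the maximal studentized ("st") global envelope: the empirical
#' and null functions are pooled and studentized bin-wise to z scores using
#' the pooled mean m(r) and standard deviation s(r); the critical value c
#' is the (n_sim + 1)(1 - alpha) order statistic -- the 380th of the 400
#' ordered maxima at alpha = 0.05 with 399 simulations -- of each
#' function's maximum absolute z over r, which gives the test exactly
#' alpha size under exchangeability. The global band
#' m(r) +/- c * s(r) is back-transformed to the statistic's scale; an
#' excursion at any single r is significant for the whole set of r. The
#' r-averaged z (signed mean of the empirical z over bins) summarizes the
#' strength and direction of departure.
#'
#' @param empirical An `fcf` (see [pair_correlation()] and friends).
#' @param nulls A list of >= 39 `fcf`s on the identical r grid.
#' @param alpha Two-sided significance level (default 0.05).
#' @return An `fs_envelope` tibble with columns `r`, `observed`,
#'   `null_mean`, `null_sd`, `lo`, `hi`, `z`; attributes `crit`,
#'   `significant`, `r_averaged_z`, `mean_abs_z`, `alpha`, `n_sim`, `kind`.
#'   Bins where s(r) = 0 (degenerate) or any value is missing get z = 0 /
#'   `NA` and are excluded from the maximum and the average (a warning is
#'   issued for degenerate bins).
#' @export
global_envelope <- function(empirical, nulls, alpha = 0.05) {
  if (length(nulls) < 39) abort("Need at least 39 null functions.")
  r <- empirical$r
  for (nl in nulls) {
    if (length(nl$r) != length(r) || any(abs(nl$r - r) > 1e-9)) {
      abort("All null functions must share the empirical r grid.")
    }
  }
  null_mat <- vapply(nulls, function(f) f$value, numeric(length(r)))
  envelope_from_matrix(r, empirical$value, null_mat, alpha,
                       kind = fcf_kind(empirical))
}

envelope_from_matrix <- function(r, observed, null_mat, alpha, kind = NULL) {
  # The empirical function joins the null functions in one exchangeable
  # pool: m(r) and s(r) are computed over all n_sim + 1 functions, every
  # function is studentized against them, and the critical value is the
  # (n_sim + 1)(1 - alpha) order statistic of all n_sim + 1 maxima of
  # |z(r)|. Rejection (the empirical maximum strictly exceeding c) then
  # has probability exactly alpha under the null.
  pool <- cbind(observed, null_mat)
  m <- rowMeans(pool)
  s <- apply(pool, 1, sd)
  valid <- is.finite(observed) & is.finite(m) & is.finite(s)
  degenerate <- valid & s <= 0
  if (any(degenerate)) {
    warn(sprintf("%d distance bin(s) have zero null variance; z set to 0 there.",
                 sum(degenerate)))
  }
  use <- valid & s > 0
  z_emp <- rep(NA_real_, length(r))
  z_emp[use] <- (observed[use] - m[use]) / s[use]
  z_emp[degenerate] <- 0

  n_sim <- ncol(null_mat)
  if (any(use)) {
    z_pool <- (pool[use, , drop = FALSE] - m[use]) / s[use]
    M <- apply(abs(z_pool), 2, max)
    k <- ceiling((n_sim + 1) * (1 - alpha))
    crit <- unname(sort(M)[k])
  } else {
    crit <- NA_real_
  }

  out <- tibble(
    r = r, observed = observed, null_mean = m, null_sd = s,
    lo = m - crit * s, hi = m + crit * s, z = z_emp
  )
  attr(out, "kind") <- kind
  attr(out, "alpha") <- alpha
  attr(out, "n_sim") <- n_sim
  attr(out, "crit") <- crit
  attr(out, "significant") <- any(use) && isTRUE(max(abs(z_emp[use])) > crit)
  attr(out, "r_averaged_z") <- mean(z_emp[valid])
  attr(out, "mean_abs_z") <- mean(abs(z_emp[valid]))
  class(out) <- c("fs_envelope", class(tibble()))
  out
}

#' @export
print.fs_envelope <- function(x, ...) {
  cat(sprintf(
    "<fs_envelope> %s: %s (crit %.2f, r-averaged z %.2f, %d sims, alpha %.3f)\n",
    attr(x, "kind") %||% "statistic",
    if (attr(x, "significant")) "significant" else "not significant",
    attr(x, "crit"), attr(x, "r_averaged_z"), attr(x, "n_sim"),
    attr(x, "alpha")))
  NextMethod()
}

#' One-call envelope test for a stem-map statistic
#'
#' Computes the empirical statistic and its null distribution with the
#' statistic-appropriate null model, reusing the pair geometry across
#' permutation nulls (labels or marks move, points do not), and returns the
#' global envelope. Statistic/null pairings:
#' `"g"` (pair correlation) with `"inhom_poisson"`; `"g_cluster"` and
#' `"g_densdep"` with `"random_label"`; `"k_mark"` and `"gamma_mark"` with
#' `"random_mark"`.
#'
#' @param map A [stem_map()].
#' @param statistic One of `"g"`, `"g_cluster"`, `"g_densdep"`,
#'   `"k_mark"`, `"gamma_mark"`.
#' @param n_sim Number of null simulations (default 399).
#' @param alpha Significance level (default 0.05).
#' @param r_max,ring Distance grid (default 15 m in 1 m annuli).
#' @param seed Integer seed for the null batch.
#' @param bandwidth Intensity bandwidth for the `inhom_poisson` null.
#' @param mark Mark column for the mark statistics (default `"dbh"`).
#' @return An `fs_envelope`.
#' @export
envelope_test <- function(map,
                          statistic = c("g", "g_cluster", "g_densdep",
                                        "k_mark", "gamma_mark"),
                          n_sim = 399, alpha = 0.05, r_max = 15, ring = 1,
                          seed = NULL, bandwidth = 20, mark = "dbh") {
  statistic <- match.arg(statistic)
  if (statistic %in% c("g_cluster", "g_densdep")) {
    both <- mortality_envelopes(map, n_sim = n_sim, alpha = alpha,
                                r_max = r_max, ring = ring, seed = seed)
    return(both[[statistic]])
  }
  breaks <- default_breaks(r_max, ring)
  if (statistic == "g") {
    emp <- pair_correlation(map, breaks = breaks)
    spec <- null_spec("inhom_poisson", n_sim = n_sim, seed = seed,
                      bandwidth = bandwidth)
    sims <- simulate_null(map, spec)
    null_mat <- vapply(sims, function(s) {
      pair_correlation(s, breaks = breaks)$value
    }, numeric(length(breaks) - 1L))
    return(envelope_from_matrix(emp$r, emp$value, null_mat, alpha, kind = "g"))
  }
  # Mark statistics under random marking: permute marks on a fixed pair table.
  w <- map_window(map)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  m <- map[[mark]]
  stat_fun <- if (statistic == "k_mark") {
    function(mm) rmark_from_pairs(pt, mm)
  } else {
    if (var(m) <= 0) abort("Mark variance is zero; mark variogram undefined.")
    function(mm) variogram_from_pairs(pt, mm, normalized = TRUE)
  }
  observed <- stat_fun(m)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_sim), function(k) stat_fun(sample(m)),
           numeric(length(breaks) - 1L))
  })
  envelope_from_matrix(bin_centers(breaks), observed, null_mat, alpha,
                       kind = statistic)
}

#' Random-labeling envelopes for both mortality difference statistics
#'
#' Computes `g_cluster` and `g_densdep` (see
#' [mortality_difference_statistics()]) and their global envelopes under
#' random labeling, sharing one pair table and one set of status
#' permutations between the two statistics.
#'
#' @inheritParams envelope_test
#' @return A named list of two `fs_envelope`s: `g_cluster`, `g_densdep`.
#' @export
mortality_envelopes <- function(map, n_sim = 399, alpha = 0.05, r_max = 15,
                                ring = 1, seed = NULL) {
  dead <- require_both_statuses(map)
  w <- map_window(map)
  breaks <- default_breaks(r_max, ring)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  area <- window_area_m2(w)
  obs <- mortality_diffs_from_pairs(pt, dead, area)
  nbin <- length(breaks) - 1L
  sims <- with_seed(seed, {
    lapply(seq_len(n_sim), function(k) {
      mortality_diffs_from_pairs(pt, sample(dead), area)
    })
  })
  r <- bin_centers(breaks)
  null_cl <- vapply(sims, `[[`, numeric(nbin), "g_cluster")
  null_dd <- vapply(sims, `[[`, numeric(nbin), "g_densdep")
  list(
    g_cluster = envelope_from_matrix(r, obs$g_cluster, null_cl, alpha,
                                     kind = "g_cluster"),
    g_densdep = envelope_from_matrix(r, obs$g_densdep, null_dd, alpha,
                                     kind = "g_densdep")
  )
}
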