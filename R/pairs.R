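# Pair geometry shared by all second-order and mark statistics.
#
# All estimators bin pairs into annuli (box kernel) delimited by `breaks`
# (default width 1 m, centers 0.5, 1.5, ..., r_max - 0.5; bins are
# left-closed, right-open, the last bin closed) and apply the Ohser
# translation edge correction for rectangular windows:
# a pair with displacement (dx, dy) in a window of sides (a, b) gets weight
# 1 / ((a - |dx|) (b - |dy|)), the reciprocal of the area over which the
# pair could have been observed. No estimate is reported at r = 0.

default_breaks <- function(r_max, ring) seq(0, r_max, by = ring)

# Unordered close pairs (i < j) with ring index and translation weight.
fs_pairs <- function(x, y, window, breaks) {
  n <- length(x)
  r_max <- breaks[length(breaks)]
  a <- window$width; b <- window$height
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  block <- 1024L
  for (start in seq(1L, max(n - 1L, 1L), by = block)) {
    rows <- start:min(start + block - 1L, n - 1L)
    dx <- outer(x[rows], x, "-")
    dy <- outer(y[rows], y, "-")
    d2 <- dx^2 + dy^2
    hit <- which(d2 <= r_max^2 & d2 > 0 &
                   outer(rows, seq_len(n), "<"), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ii <- c(ii, rows[hit[, 1]])
      jj <- c(jj, hit[, 2])
      dd <- c(dd, sqrt(d2[hit]))
    }
  }
  ring <- findInterval(dd, breaks, rightmost.closed = TRUE)
  keep <- ring >= 1 & ring <= length(breaks) - 1
  ii <- ii[keep]; jj <- jj[keep]; ring <- ring[keep]; dd <- dd[keep]
  w <- 1 / ((a - abs(x[ii] - x[jj])) * (b - abs(y[ii] - y[jj])))
  nbins <- length(breaks) - 1L
  list(i = ii, j = jj, ring = ring, w = w, d = dd,
       nbins = nbins, breaks = breaks,
       ring_area = pi * diff(breaks^2),
       n = n, area = a * b)
}

ring_sum <- function(values, ring, nbins) {
  out <- numeric(nbins)
  if (length(values) > 0) {
    s <- rowsum(values, ring)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# Bivariate (or univariate, when both subsets are everything) pair
# correlation from a precomputed pair table. `lambda1`, `lambda2` are
# per-point intensity vectors (constant n/A in the homogeneous case).
pcf_from_pairs <- function(pt, in1, in2, lambda1, lambda2) {
  fwd <- in1[pt$i] & in2[pt$j]
  rev <- in1[pt$j] & in2[pt$i]
  contrib <- pt$w * (fwd / (lambda1[pt$i] * lambda2[pt$j]) +
                       rev / (lambda1[pt$j] * lambda2[pt$i]))
  ring_sum(contrib, pt$ring, pt$nbins) / pt$ring_area
}

new_fcf <- function(r, value, kind, pt, window, extra = list()) {
  out <- tibble(r = r, value = value)
  attr(out, "kind") <- kind
  attr(out, "breaks") <- pt$breaks
  attr(out, "correction") <- "translation"
  attr(out, "n") <- pt$n
  attr(out, "window") <- window
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("fcf", class(tibble()))
  out
}

#' @export
print.fcf <- function(x, ...) {
  cat(sprintf("<fcf> %s, %d distance bins, translation correction, n = %d\n",
              attr(x, "kind") %||% "?", nrow(x), attr(x, "n")))
  NextMethod()
}

fcf_kind <- function(x) attr(x, "kind", exact = TRUE)

#' Univariate pair correlation function
#'
#' Estimates g(r), the density-normalized expected number of trees at
#' distance r from a typical tree: 1 under complete spatial randomness,
#' above 1 for aggregated and below 1 for uniform/inhibited patterns.
#' The estimator sums, over ordered pairs whose distance falls in each
#' annulus, the reciprocal of the translation edge-correction area and of
#' the intensity at both points, divided by the annulus area; with constant
#' intensity n/A this is the classical homogeneous estimator, and with a
#' supplied [estimate_intensity()] field it is the inhomogeneous estimator
#' (expectation 1 for an inhomogeneous Poisson process of that intensity).
#'
#' @param map A [stem_map()] with at least 2 trees.
#' @param r_max Maximum distance (m), default 15.
#' @param ring Annulus width (m), default 1.
#' @param intensity `NULL` for the homogeneous estimator, or an
#'   `intensity_field` for the inhomogeneous one (looked up at the nearest
#'   grid cell, floored at 1e-9).
#' @param breaks Optional custom bin breaks (overrides `r_max`/`ring`).
#' @return An `fcf` tibble with columns `r` (bin centers) and `value`;
#'   empty annuli give 0 (no pairs observed).
#' @export
pair_correlation <- function(map, r_max = 15, ring = 1, intensity = NULL,
                             breaks = NULL) {
  if (nrow(map) < 2) abort("Need at least 2 trees for a pair correlation.")
  w <- map_window(map)
  check_rmax(r_max, w)
  breaks <- breaks %||% default_breaks(r_max, ring)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  lam <- point_intensity(map, intensity)
  everything <- rep(TRUE, pt$n)
  val <- pcf_from_pairs(pt, everything, everything, lam, lam)
  new_fcf(bin_centers(breaks), val,
          if (is.null(intensity)) "g" else "g_inhom", pt, w)
}

point_intensity <- function(map, intensity) {
  if (is.null(intensity)) {
    rep(nrow(map) / window_area_m2(map_window(map)), nrow(map))
  } else {
    intensity_at(intensity, map$x, map$y)
  }
}

check_rmax <- function(r_max, window) {
  if (r_max > min(window$width, window$height) / 2) {
    warn("r_max exceeds half the shorter window side; estimates will be noisy.")
  }
}

#' Bivariate pair correlation function
#'
#' Counts type-2 trees at distance r from type-1 trees, normalized by the
#' type-2 density: g12(r) is 1 when the two components are independent.
#' Not symmetric-normalized; a tree may belong to both subsets (self-pairs
#' are excluded), so `type2` may be all trees.
#'
#' @param map A [stem_map()].
#' @param type1,type2 Logical vectors over the rows of `map` (or tree-id
#'   character vectors) selecting the two subsets; both must be non-empty.
#' @inheritParams pair_correlation
#' @return An `fcf` tibble.
#' @export
bivariate_pair_correlation <- function(map, type1, type2, r_max = 15,
                                       ring = 1, breaks = NULL) {
  w <- map_window(map)
  check_rmax(r_max, w)
  breaks <- breaks %||% default_breaks(r_max, ring)
  in1 <- as_subset(map, type1); in2 <- as_subset(map, type2)
  if (!any(in1) || !any(in2)) {
    abort("Both subsets must be non-empty for a bivariate pair correlation.")
  }
  pt <- fs_pairs(map$x, map$y, w, breaks)
  A <- window_area_m2(w)
  lam1 <- rep(sum(in1) / A, pt$n)
  lam2 <- rep(sum(in2) / A, pt$n)
  val <- pcf_from_pairs(pt, in1, in2, lam1, lam2)
  new_fcf(bin_centers(breaks), val, "g12", pt, w)
}

as_subset <- function(map, sel) {
  if (is.logical(sel)) {
    stopifnot(length(sel) == nrow(map))
    return(sel)
  }
  map$id %in% sel
}

#' Mortality clustering and density-dependence statistics
#'
#' Two differences of bivariate pair correlations computed on a stem map
#' with alive/killed statuses:
#' * `g_cluster(r) = g_dead,dead(r) - g_alive,dead(r)`: positive when
#'   fire-killed trees are more common around other killed trees than
#'   around survivors, i.e. mortality is clustered.
#' * `g_densdep(r) = g_dead,all(r) - g_alive,all(r)`: positive when dead
#'   trees sat in denser neighborhoods than survivors, i.e. mortality is
#'   density-dependent.
#'
#' The null expectation of both is 0 under random labeling.
#'
#' @param map A [stem_map()] whose `status` column contains both `"alive"`
#'   and `"killed"`.
#' @inheritParams pair_correlation
#' @return A named list of two `fcf` tibbles, `g_cluster` and `g_densdep`.
#' @export
mortality_difference_statistics <- function(map, r_max = 15, ring = 1,
                                            breaks = NULL) {
  dead <- require_both_statuses(map)
  w <- map_window(map)
  breaks <- breaks %||% default_breaks(r_max, ring)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  vals <- mortality_diffs_from_pairs(pt, dead, window_area_m2(w))
  list(
    g_cluster = new_fcf(bin_centers(breaks), vals$g_cluster, "g_cluster", pt, w),
    g_densdep = new_fcf(bin_centers(breaks), vals$g_densdep, "g_densdep", pt, w)
  )
}

require_both_statuses <- function(map) {
  if (!"status" %in% names(map)) abort("Map has no `status` column.")
  dead <- map$status == "killed"
  if (!any(dead) || all(dead)) {
    abort("Mortality statistics need both alive and killed trees.")
  }
  dead
}

# Shared fast path: both mortality difference statistics from a pair table
# and a logical `dead` vector. Used directly by the random-labeling
# envelope so relabelings reuse the pair geometry.
mortality_diffs_from_pairs <- function(pt, dead, area) {
  alive <- !dead
  n_d <- sum(dead); n_a <- sum(alive); n <- pt$n
  lam_d <- rep(n_d / area, n); lam_a <- rep(n_a / area, n)
  lam_all <- rep(n / area, n)
  g_dd <- pcf_from_pairs(pt, dead, dead, lam_d, lam_d)
  g_ad <- pcf_from_pairs(pt, alive, dead, lam_a, lam_d)
  all_pts <- rep(TRUE, n)
  g_dall <- pcf_from_pairs(pt, dead, all_pts, lam_d, lam_all)
  g_aall <- pcf_from_pairs(pt, alive, all_pts, lam_a, lam_all)
  list(g_cluster = g_dd - g_ad, g_densdep = g_dall - g_aall)
}

#' r-mark correlation function
#'
#' The mean mark (tree dbh by default) of trees found at distance r from
#' another tree, in mark units. Values below the global mean mark at short
#' r indicate that close neighbors tend to be small trees.
#'
#' @param map A [stem_map()] with >= 2 trees.
#' @param mark Column name of the quantitative mark (default `"dbh"`).
#' @inheritParams pair_correlation
#' @return An `fcf` tibble; the global mean mark is attached as attribute
#'   `mark_mean`. Annuli with no pairs are `NA` (undefined mean).
#' @export
r_mark_correlation <- function(map, mark = "dbh", r_max = 15, ring = 1,
                               breaks = NULL) {
  if (nrow(map) < 2) abort("Need at least 2 trees.")
  w <- map_window(map)
  breaks <- breaks %||% default_breaks(r_max, ring)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  m <- map[[mark]]
  val <- rmark_from_pairs(pt, m)
  new_fcf(bin_centers(breaks), val, "k_mark", pt, w,
          extra = list(mark = mark, mark_mean = mean(m)))
}

rmark_from_pairs <- function(pt, m) {
  tot <- ring_sum(m[pt$i] + m[pt$j], pt$ring, pt$nbins)
  cnt <- ring_sum(rep(2, length(pt$ring)), pt$ring, pt$nbins)
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Mark variogram
#'
#' The semivariance of marks between trees r apart: the mean over pairs of
#' `0.5 * (m_i - m_j)^2`. When `normalized = TRUE` (default) it is divided
#' by the sample mark variance, so spatially independent marks give an
#' expectation of 1 at every distance; values below 1 at short r mean
#' nearby trees are similar in size.
#'
#' @inheritParams r_mark_correlation
#' @param normalized Divide by the sample mark variance (default `TRUE`).
#' @return An `fcf` tibble; annuli with no pairs are `NA`.
#' @export
mark_variogram <- function(map, mark = "dbh", r_max = 15, ring = 1,
                           normalized = TRUE, breaks = NULL) {
  if (nrow(map) < 2) abort("Need at least 2 trees.")
  m <- map[[mark]]
  if (normalized && var(m) <= 0) {
    abort("Mark variance is zero; use normalized = FALSE.")
  }
  w <- map_window(map)
  breaks <- breaks %||% default_breaks(r_max, ring)
  pt <- fs_pairs(map$x, map$y, w, breaks)
  val <- variogram_from_pairs(pt, m, normalized)
  new_fcf(bin_centers(breaks), val,
          if (normalized) "gamma_mark" else "gamma_mark_raw", pt, w,
          extra = list(mark = mark, normalized = normalized))
}

variogram_from_pairs <- function(pt, m, normalized) {
  sv <- 0.5 * (m[pt$i] - m[pt$j])^2
  tot <- ring_sum(sv, pt$ring, pt$nbins)
  cnt <- ring_sum(rep(1, length(pt$ring)), pt$ring, pt$nbins)
  val <- ifelse(cnt > 0, tot / cnt, NA_real_)
  if (normalized) val <- val / var(m)
  val
}
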