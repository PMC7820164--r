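#' Identify tree groups by limiting-distance chaining
#'
#' Two trees belong to the same group when they are connected by a chain of
#' steps each no longer than the linkage distance (inclusive: a pair at
#' exactly the linkage distance is chained). Groups are the connected
#' components of the graph joining all pairs at Euclidean distance <=
#' `linkage`; isolated trees form singleton groups. The default 6 m
#' limiting distance is the conventional crown-scale neighborhood for
#' dry-forest group delineation.
#'
#' @param map A non-empty [stem_map()].
#' @param linkage Limiting distance in meters (> 0), default 6.
#' @return A `tree_groups` object: list with `trees` (tibble `id`,
#'   `group`), `groups` (tibble `group`, `n_trees`, `basal_area` in m^2,
#'   `size_class`), and `linkage`.
#' @export
identify_groups <- function(map, linkage = 6) {
  assert_number(linkage, "linkage", lower = 1e-12)
  if (nrow(map) == 0) abort("Cannot identify groups on an empty map.")
  n <- nrow(map)
  edges <- close_pairs_within(map$x, map$y, linkage)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  comp <- igraph::components(g)$membership
  trees <- tibble(id = map$id, group = as.integer(comp))
  ba <- pi * (map$dbh / 200)^2
  groups <- dplyr::summarise(
    dplyr::group_by(tibble(group = trees$group, ba = ba), .data$group),
    n_trees = dplyr::n(), basal_area = sum(.data$ba), .groups = "drop"
  )
  groups$size_class <- group_size_class(groups$n_trees)
  structure(list(trees = trees, groups = groups, linkage = linkage),
            class = "tree_groups")
}

# All unordered pairs (i < j) at distance <= radius, including coincident
# points (distance 0 chains trees into one group).
close_pairs_within <- function(x, y, radius) {
  n <- length(x)
  ii <- integer(0); jj <- integer(0)
  block <- 1024L
  if (n >= 2) {
    for (start in seq(1L, n - 1L, by = block)) {
      rows <- start:min(start + block - 1L, n - 1L)
      d2 <- outer(x[rows], x, "-")^2 + outer(y[rows], y, "-")^2
      hit <- which(d2 <= radius^2 & outer(rows, seq_len(n), "<"),
                   arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ii <- c(ii, rows[hit[, 1]])
        jj <- c(jj, hit[, 2])
      }
    }
  }
  tibble(i = ii, j = jj)
}

#' Group size classes
#'
#' Bins group sizes (trees per group) into the standard classes: single
#' trees, 2-4, 5-9, 10-19, and 20+ trees per group.
#'
#' @param n_trees Integer vector of group sizes (>= 1).
#' @return An ordered factor with levels `single`, `2-4`, `5-9`, `10-19`,
#'   `20+`.
#' @export
group_size_class <- function(n_trees) {
  cut(n_trees, breaks = c(0, 1, 4, 9, 19, Inf),
      labels = c("single", "2-4", "5-9", "10-19", "20+"),
      ordered_result = TRUE)
}

#' @export
print.tree_groups <- function(x, ...) {
  cat(sprintf("<tree_groups> %d trees in %d groups (linkage %g m)\n",
              nrow(x$trees), nrow(x$groups), x$linkage))
  print(table(x$groups$size_class))
  invisible(x)
}

#' Group sizes
#'
#' @param groups A `tree_groups` object.
#' @return Integer vector of trees per group (one entry per group).
#' @export
group_sizes <- function(groups) groups$groups$n_trees

#' @export
tidy.tree_groups <- function(x, ...) x$groups

#' @export
glance.tree_groups <- function(x, ...) {
  sz <- group_sizes(x)
  tibble(
    n_trees = nrow(x$trees), n_groups = length(sz),
    mean_size = mean(sz), median_size = median(sz),
    cv_size = sd(sz) / mean(sz),
    prop_multi = mean(sz > 1), linkage = x$linkage
  )
}

#' Pre- to post-fire flow of trees between group size classes
#'
#' Survivors of a fire are regrouped from scratch at the same linkage
#' distance; each surviving tree contributes one count from its prefire
#' size class to its postfire size class, and each killed tree one count
#' from its prefire class to `"killed"`. Row sums therefore equal the
#' prefire class totals (mass balance).
#'
#' @param pre A `tree_groups` from the prefire map.
#' @param post_map A [stem_map()] with a `status` column whose trees are a
#'   subset of the prefire trees.
#' @param linkage Limiting distance (m) used to regroup survivors.
#' @return A `group_flow` object: list with `matrix` (rows = prefire
#'   classes, columns = postfire classes plus `"killed"`), and `flows`
#'   (long tibble `from_class`, `to_class`, `n`).
#' @export
group_flow <- function(pre, post_map, linkage = 6) {
  stopifnot(inherits(pre, "tree_groups"))
  if (!"status" %in% names(post_map)) abort("post_map needs a `status` column.")
  unknown <- setdiff(post_map$id, pre$trees$id)
  if (length(unknown) > 0) {
    abort(sprintf("post_map has %d tree id(s) not present prefire, e.g.: %s.",
                  length(unknown), paste(head(unknown, 5), collapse = ", ")))
  }
  classes <- levels(group_size_class(1))
  pre_class <- pre$groups$size_class[match(pre$trees$group, pre$groups$group)]
  pre_class <- setNames(as.character(pre_class), pre$trees$id)

  survivors <- post_map[post_map$status == "alive", , drop = FALSE]
  to_class <- setNames(rep("killed", nrow(post_map)), post_map$id)
  if (nrow(survivors) > 0) {
    post_groups <- identify_groups(restamp(survivors, post_map), linkage)
    surv_class <- post_groups$groups$size_class[
      match(post_groups$trees$group, post_groups$groups$group)]
    to_class[post_groups$trees$id] <- as.character(surv_class)
  }
  from <- factor(pre_class[post_map$id], levels = classes)
  to <- factor(to_class[post_map$id], levels = c(classes, "killed"))
  mat <- table(from, to)
  flows <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  names(flows) <- c("from_class", "to_class", "n")
  structure(list(matrix = unclass(mat), flows = flows), class = "group_flow")
}

#' @export
print.group_flow <- function(x, ...) {
  cat("<group_flow> trees by prefire class (rows) -> postfire class (cols)\n")
  print(x$matrix)
  invisible(x)
}

#' @export
tidy.group_flow <- function(x, ...) x$flows

#' Signed likelihood-ratio test for equality of coefficients of variation
#'
#' Tests H0: CV(a) = CV(b) under independent normal models
#' `N(mu_i, (tau_i mu_i)^2)`. The deviance compares the unconstrained fit
#' with the fit profiled over a common CV tau (the inner maximization over
#' each mean has a closed form), and the signed root
#' `R = sign(cv_a - cv_b) * sqrt(deviance)` is referred to N(0, 1)
#' (equivalently the deviance to chi-squared(1)). `correction =
#' "bootstrap"` additionally recenters R by its parametric-bootstrap null
#' mean (samples drawn from the fitted common-CV model), a small-sample
#' mean adjustment; the default is no correction, which keeps the exact
#' identity p = 1 when the two samples coincide.
#'
#' @param a,b Numeric samples (>= 2 values each, positive means).
#' @param correction `"none"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates for the correction (default 200).
#' @param seed Seed for the bootstrap draw.
#' @return A list with `statistic` (signed root), `deviance`, `p.value`,
#'   `cv` (the two estimated CVs), and `common_cv`.
#' @export
cv_slrt_test <- function(a, b, correction = c("none", "bootstrap"),
                         n_boot = 200, seed = 1) {
  correction <- match.arg(correction)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("Need >= 2 values per sample.")
  fit <- slrt_fit(a, b)
  R <- fit$statistic
  if (correction == "bootstrap" && is.finite(R)) {
    mu <- fit$mu_hat; tau <- fit$common_cv
    Rs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(k) {
        slrt_fit(rnorm(length(a), mu[1], abs(tau * mu[1])),
                 rnorm(length(b), mu[2], abs(tau * mu[2])))$statistic
      }, numeric(1))
    })
    R <- R - mean(Rs, na.rm = TRUE)
  }
  p <- 2 * pnorm(-abs(R))
  list(statistic = R, deviance = fit$deviance, p.value = p,
       cv = fit$cv, common_cv = fit$common_cv)
}

# Deviance and signed root for the common-CV model. Degenerate samples
# (zero variance in both) give deviance 0, p = 1 by convention.
slrt_fit <- function(a, b) {
  samples <- list(a, b)
  n <- vapply(samples, length, integer(1))
  xbar <- vapply(samples, mean, numeric(1))
  s2 <- vapply(samples, function(x) sum((x - mean(x))^2) / length(x),
               numeric(1))
  cv <- sqrt(s2) / xbar
  if (all(s2 <= 0)) {
    return(list(statistic = 0, deviance = 0, cv = cv, common_cv = 0,
                mu_hat = xbar))
  }
  l_unres <- sum(-n / 2 * (log(2 * pi * s2) + 1))

  sum_x <- vapply(samples, sum, numeric(1))
  sum_x2 <- vapply(samples, function(x) sum(x^2), numeric(1))
  prof <- function(log_tau) {
    tau2 <- exp(2 * log_tau)
    ll <- 0
    for (i in 1:2) {
      mu <- (-sum_x[i] + sqrt(sum_x[i]^2 + 4 * n[i] * tau2 * sum_x2[i])) /
        (2 * n[i] * tau2)
      sig2 <- tau2 * mu^2
      ll <- ll + (-n[i] / 2 * log(2 * pi * sig2) -
                    (sum_x2[i] - 2 * mu * sum_x[i] + n[i] * mu^2) / (2 * sig2))
    }
    ll
  }
  cv_pos <- cv[is.finite(cv) & cv > 0]
  lo <- log(min(cv_pos) / 20); hi <- log(max(abs(cv_pos)) * 20)
  opt <- optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)
  deviance <- max(0, 2 * (l_unres - opt$objective))
  mu_hat <- {
    tau2 <- exp(2 * opt$maximum)
    (-sum_x + sqrt(sum_x^2 + 4 * n * tau2 * sum_x2)) / (2 * n * tau2)
  }
  list(statistic = sign(cv[1] - cv[2]) * sqrt(deviance),
       deviance = deviance, cv = cv, common_cv = exp(opt$maximum),
       mu_hat = mu_hat)
}

#' Compare two group-size distributions
#'
#' Compares the location (rank test) and relative variability (CV equality,
#' [cv_slrt_test()]) of two samples of group sizes, with Bonferroni
#' adjustment for a family of comparisons (default 3, one per plot). The
#' rank test defaults to the unpaired rank-sum form -- group samples from
#' two eras are structurally unpaired -- with the paired signed-rank form
#' available via `paired = TRUE`.
#'
#' @param sizes_a,sizes_b Numeric vectors of group sizes (>= 2 each).
#' @param n_comparisons Bonferroni family size (default 3).
#' @param paired Use the paired signed-rank form (requires equal lengths).
#' @param slrt_correction Passed to [cv_slrt_test()].
#' @return A `group_comparison` object (list) with medians, CVs, the
#'   Wilcoxon and SLRT statistics and raw plus Bonferroni-adjusted p
#'   values; `tidy()` returns it as a tibble.
#' @export
compare_group_sizes <- function(sizes_a, sizes_b, n_comparisons = 3,
                                paired = FALSE,
                                slrt_correction = "none") {
  if (length(sizes_a) < 2 || length(sizes_b) < 2) {
    abort("Need at least 2 groups per sample.")
  }
  wt <- suppressWarnings(
    wilcox.test(sizes_a, sizes_b, paired = paired)
  )
  st <- cv_slrt_test(sizes_a, sizes_b, correction = slrt_correction)
  bonf <- function(p) min(1, n_comparisons * p)
  structure(
    list(
      median = c(a = median(sizes_a), b = median(sizes_b)),
      mean = c(a = mean(sizes_a), b = mean(sizes_b)),
      cv = c(a = sd(sizes_a) / mean(sizes_a),
             b = sd(sizes_b) / mean(sizes_b)),
      wilcoxon = list(statistic = unname(wt$statistic), p.value = wt$p.value,
                      p.adjusted = bonf(wt$p.value), paired = paired),
      slrt = list(statistic = st$statistic, p.value = st$p.value,
                  p.adjusted = bonf(st$p.value)),
      n_comparisons = n_comparisons
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  median size: %.2f vs %.2f | CV: %.2f vs %.2f\n",
              x$median["a"], x$median["b"], x$cv["a"], x$cv["b"]))
  cat(sprintf("  %s rank test: p = %.4f (adj %.4f)\n",
              if (x$wilcoxon$paired) "signed-rank" else "rank-sum",
              x$wilcoxon$p.value, x$wilcoxon$p.adjusted))
  cat(sprintf("  CV SLRT: R = %.3f, p = %.4f (adj %.4f)\n",
              x$slrt$statistic, x$slrt$p.value, x$slrt$p.adjusted))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    test = c("wilcoxon", "cv_slrt"),
    statistic = c(x$wilcoxon$statistic, x$slrt$statistic),
    p.value = c(x$wilcoxon$p.value, x$slrt$p.value),
    p.adjusted = c(x$wilcoxon$p.adjusted, x$slrt$p.adjusted)
  )
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    median_a = unname(x$median["a"]), median_b = unname(x$median["b"]),
    cv_a = unname(x$cv["a"]), cv_b = unname(x$cv["b"]),
    wilcoxon_p = x$wilcoxon$p.value, slrt_p = x$slrt$p.value,
    wilcoxon_p_adj = x$wilcoxon$p.adjusted, slrt_p_adj = x$slrt$p.adjusted
  )
}
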