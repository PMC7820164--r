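test_that("chaining joins trees through intermediate neighbors, inclusively", {
  m <- toy_map(c(0.5, 5.5, 11.5, 30.5), rep(1, 4), width = 50)
  # gaps: 5 m, 6 m (exactly the linkage, inclusive), 19 m
  gp <- identify_groups(m, linkage = 6)
  expect_equal(canonical_partition(gp$trees$group), c(1, 1, 1, 2))
  expect_equal(sort(group_sizes(gp)), c(1, 3))

  # at linkage 5.999 the 6 m step breaks
  gp2 <- identify_groups(m, linkage = 5.999)
  expect_equal(sort(group_sizes(gp2)), c(1, 1, 2))

  far <- toy_map(c(0, 10, 20, 30), c(0, 10, 20, 30), width = 50)
  expect_true(all(group_sizes(identify_groups(far, 6)) == 1))
  expect_error(identify_groups(far, 0), "linkage")
})

test_that("group partition matches brute-force transitive closure", {
  withr::local_seed(33)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    m <- toy_map(runif(n, 0, 60), runif(n, 0, 60), width = 60)
    gp <- identify_groups(m, linkage = 6)
    oracle <- naive_groups(m$x, m$y, 6)
    expect_equal(canonical_partition(gp$trees$group),
                 canonical_partition(oracle))
  }
})

test_that("group metadata: partition, basal area, size classes", {
  m <- toy_map(c(1, 3, 5, 40), c(1, 1, 1, 40), dbh = c(20, 30, 40, 50),
               width = 60)
  gp <- identify_groups(m)
  expect_equal(sum(gp$groups$n_trees), 4)
  expect_equal(sort(gp$groups$n_trees), c(1, 3))
  big <- gp$groups[gp$groups$n_trees == 3, ]
  expect_equal(big$basal_area, sum(pi * (c(20, 30, 40) / 200)^2))
  expect_equal(as.character(big$size_class), "2-4")
  expect_equal(levels(group_size_class(1)),
               c("single", "2-4", "5-9", "10-19", "20+"))
  expect_equal(as.character(group_size_class(c(1, 2, 4, 5, 9, 10, 19, 20, 60))),
               c("single", "2-4", "2-4", "5-9", "5-9", "10-19", "10-19",
                 "20+", "20+"))
})

test_that("linkage is monotone: longer distances only merge groups", {
  withr::local_seed(35)
  m <- toy_map(runif(80, 0, 60), runif(80, 0, 60), width = 60)
  g_small <- identify_groups(m, 4)$trees$group
  g_large <- identify_groups(m, 8)$trees$group
  # every 4 m group sits inside one 8 m group
  for (g in unique(g_small)) {
    expect_length(unique(g_large[g_small == g]), 1)
  }
})

test_that("flow matrices balance mass and handle the extremes", {
  withr::local_seed(37)
  m <- toy_map(runif(60, 0, 50), runif(60, 0, 50), width = 50)
  pre <- identify_groups(m)

  none <- restamp_with(m, status = rep("alive", 60))
  f0 <- group_flow(pre, none)
  expect_equal(sum(f0$matrix[, "killed"]), 0)
  off_diag <- f0$matrix[, setdiff(colnames(f0$matrix), "killed")]
  expect_equal(sum(diag(off_diag)), 60) # regrouping identical => diagonal

  all_dead <- restamp_with(m, status = rep("killed", 60))
  f1 <- group_flow(pre, all_dead)
  expect_equal(sum(f1$matrix[, "killed"]), 60)
  expect_equal(sum(f1$matrix) - sum(f1$matrix[, "killed"]), 0)
})

test_that("a 6-tree toy reproduces the hand-enumerated flow matrix", {
  # group A: five trees in a 6 m chain; group B: a singleton far away.
  # killing trees 2 and 4 splits A's survivors into {1} and {3? no:}
  # chain x = 0, 5, 10, 15, 20: kill x=5 and x=15 -> survivors 0, 10, 20
  # pairwise 10 m apart: three singletons. B survives as a singleton.
  m <- toy_map(c(0.5, 5.5, 10.5, 15.5, 20.5, 45.5), rep(1, 6), width = 60)
  pre <- identify_groups(m)
  expect_equal(sort(group_sizes(pre)), c(1, 5))
  post <- restamp_with(m, status = c("alive", "killed", "alive", "killed",
                                     "alive", "alive"))
  fl <- group_flow(pre, post)
  expect_equal(fl$matrix["5-9", "single"], 3)
  expect_equal(fl$matrix["5-9", "killed"], 2)
  expect_equal(fl$matrix["single", "single"], 1)
  expect_equal(sum(fl$matrix), 6)
  expect_equal(sum(fl$matrix["5-9", ]), 5)

  # survivors can split but never merge across prefire groups
  expect_equal(sum(fl$matrix[, "2-4"]), 0)

  stranger <- stem_map(data.frame(id = 99, x = 1, y = 1, species = "X",
                                  dbh = 10, status = "alive"),
                       plot_window(0, 60, 0, 60))
  expect_error(group_flow(pre, stranger), "not present")
})

test_that("identical samples give null comparisons", {
  s <- c(1, 1, 2, 4, 9)
  cmp <- compare_group_sizes(s, s)
  expect_equal(cmp$slrt$statistic, 0, tolerance = 1e-3)
  expect_equal(cmp$slrt$p.value, 1, tolerance = 1e-3)
  expect_equal(cmp$wilcoxon$p.value, 1)
  expect_equal(cmp$slrt$p.adjusted, 1)
})

test_that("the CV SLRT matches an independent grid/profile oracle", {
  a <- c(1, 1, 2, 4, 9)
  b <- c(1, 2, 2, 3)
  fit <- cv_slrt_test(a, b)
  oracle <- naive_cv_slrt(a, b)
  expect_equal(fit$statistic, oracle$statistic, tolerance = 1e-5)
  expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-5)
  expect_equal(fit$p.value, oracle$p.value, tolerance = 1e-5)

  # a second, asymmetric pair; sign follows cv(a) - cv(b)
  a2 <- c(5, 6, 7, 8, 30)
  b2 <- c(9.5, 10, 10.5, 11)
  fit2 <- cv_slrt_test(a2, b2)
  oracle2 <- naive_cv_slrt(a2, b2)
  expect_equal(fit2$statistic, oracle2$statistic, tolerance = 1e-4)
  expect_gt(fit2$statistic, 0)
})

test_that("the SLRT holds its size under equal CVs", {
  withr::local_seed(39)
  rejections <- vapply(1:300, function(k) {
    a <- rnorm(50, 10, 2); b <- rnorm(50, 20, 4) # both CV 0.2
    cv_slrt_test(a, b)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.035)
})

test_that("bootstrap mean correction stays close to the uncorrected test at n = 50", {
  withr::local_seed(40)
  a <- rnorm(50, 10, 2); b <- rnorm(50, 20, 5)
  plain <- cv_slrt_test(a, b)
  boot <- cv_slrt_test(a, b, correction = "bootstrap", n_boot = 100, seed = 5)
  expect_lt(abs(plain$statistic - boot$statistic), 0.5)
})

test_that("comparisons report Bonferroni-adjusted p values", {
  withr::local_seed(41)
  a <- rpois(40, 3) + 1
  b <- rpois(40, 6) + 1
  cmp <- compare_group_sizes(a, b, n_comparisons = 3)
  expect_equal(cmp$wilcoxon$p.adjusted, min(1, 3 * cmp$wilcoxon$p.value))
  expect_equal(cmp$slrt$p.adjusted, min(1, 3 * cmp$slrt$p.value))
  td <- tidy(cmp)
  expect_equal(nrow(td), 2)
  expect_true(all(td$p.adjusted >= td$p.value))
  expect_error(compare_group_sizes(1, c(1, 2)), "2 groups")
})
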