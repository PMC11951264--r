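test_that("PCoA reproduces Euclidean configurations", {
  # collinear points: one positive axis recovering the spacing
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  ord <- pcoa(d)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1L)
  rec <- as.matrix(dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)

  # planar 4-point configuration: embedded distances equal the input
  set.seed(21)
  pts <- matrix(rnorm(8), 4, 2)
  d2 <- as.matrix(dist(pts))
  ord2 <- pcoa(d2)
  expect_equal(unname(as.matrix(dist(ord2$coordinates))), unname(d2),
               tolerance = 1e-8)
  expect_equal(sum(ord2$proportion_explained), 1)

  # agreement with classical MDS
  cmd <- stats::cmdscale(d2, k = 2, eig = TRUE)
  expect_equal(abs(ord2$coordinates[, 1:2]), abs(cmd$points),
               ignore_attr = TRUE, tolerance = 1e-8)

  zero <- matrix(0, 3, 3)
  expect_equal(ncol(pcoa(zero)$coordinates), 0L)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), class = "hfa_value_error")
})

test_that("PERMANOVA matches exact enumeration and the direct-F oracle", {
  set.seed(31)
  pts <- matrix(rnorm(12), 6, 2)
  pts[4:6, 1] <- pts[4:6, 1] + 1.5
  d <- as.matrix(dist(pts))
  groups <- rep(c("a", "b"), each = 3)
  res <- permanova(d, data.frame(g = groups), exact = TRUE)
  f_obs <- res$table$pseudo_f[1]

  # independent F from within/between squared distances
  expect_equal(f_obs, oracle_permanova_f(d, groups), tolerance = 1e-10)

  # exact p: enumerate all 720 label permutations with the oracle
  perms <- NULL
  rec <- function(v, rest) {
    if (length(rest) == 0) return(list(v))
    unlist(lapply(seq_along(rest),
                  function(i) rec(c(v, rest[i]), rest[-i])),
           recursive = FALSE)
  }
  allp <- rec(integer(), 1:6)
  fs <- vapply(allp, function(p) oracle_permanova_f(d, groups[p]), numeric(1))
  expect_equal(res$table$p_value[1], mean(fs >= f_obs - 1e-12),
               tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R-squared", {
  skip_if_not_installed("vegan")
  set.seed(32)
  m <- matrix(rpois(200, 10), nrow = 10)
  colnames(m) <- paste0("s", 1:20)
  rownames(m) <- paste0("t", 1:10)
  fac <- data.frame(g1 = rep(c("x", "y"), 10),
                    g2 = rep(c("u", "v"), each = 10))
  d <- bray_curtis_matrix(m)
  mine <- permanova(d, fac, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g1 + g2, data = fac,
                        permutations = 99, by = "terms")
  expect_equal(mine$table$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(mine$table$r_squared[1:2], ref$R2[1:2], tolerance = 1e-8)
  # sequential R2 plus residual sums to one
  expect_equal(sum(mine$table$r_squared[1:3]), 1, tolerance = 1e-9)

  expect_error(permanova(d, data.frame(g = rep("x", 20))),
               class = "hfa_degenerate_factor_error")
})

test_that("a factor explaining all structure takes R-squared to one", {
  base <- matrix(rpois(20, 20), nrow = 10)
  m <- cbind(base[, rep(1, 4)], base[, rep(2, 4)]) +
    matrix(rpois(80, 1), nrow = 10)
  colnames(m) <- paste0("s", 1:8)
  d <- bray_curtis_matrix(m)
  res <- permanova(d, data.frame(g = rep(c("a", "b"), each = 4)),
                   n_perm = 99, seed = 2)
  expect_gt(res$table$r_squared[1], 0.9)
})

test_that("one-way ANOVA omnibus matches the textbook F computation", {
  set.seed(41)
  values <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3))
  groups <- rep(c("a", "b", "c"), each = 5)
  res <- one_way_anova_bonferroni(values, groups)
  # textbook: SSB/(k-1) over SSW/(n-k)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / 2) / (ssw / 12)
  expect_equal(res$f, f, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pf(f, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Bonferroni letters separate only truly shifted groups", {
  # identical group distributions: F = 0, one shared letter
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b", "c", "d"), each = 3)
  res <- one_way_anova_bonferroni(v, g)
  expect_equal(res$f, 0)
  expect_true(all(res$letters == res$letters[1]))

  # one group shifted by 10 sd gets its own letter
  set.seed(42)
  v2 <- c(rnorm(6), rnorm(6), rnorm(6) + 10)
  g2 <- rep(c("a", "b", "c"), each = 6)
  res2 <- one_way_anova_bonferroni(v2, g2)
  expect_false(res2$letters["c"] %in% res2$letters[c("a", "b")])
  expect_equal(res2$letters["a"], res2$letters["b"], ignore_attr = TRUE)

  # two groups: the single Bonferroni-adjusted p equals the unadjusted one
  v3 <- c(rnorm(5), rnorm(5, 2))
  g3 <- rep(c("a", "b"), each = 5)
  res3 <- one_way_anova_bonferroni(v3, g3)
  raw <- stats::pairwise.t.test(v3, g3, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value[1, 1]
  expect_equal(res3$pairwise$p_adjusted, raw)

  expect_error(one_way_anova_bonferroni(c(1, 2, 3), c("a", "a", "b")),
               class = "hfa_insufficient_data_error")
})

test_that("two-sample t behaves at the edges and detects large shifts", {
  res <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  res2 <- two_sample_t(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$mean_difference, -100)

  # equal variances and n: Student and Welch coincide
  a <- c(1.2, 2.1, 2.9); b <- c(4.2, 5.1, 5.9)
  expect_equal(two_sample_t(a, b, "welch")$p_value,
               two_sample_t(a, b, "student")$p_value, tolerance = 1e-12)

  expect_message(res3 <- two_sample_t(c(2, 2, 2), c(2, 2, 2)), "convention")
  expect_equal(res3$p_value, 1)
  expect_error(two_sample_t(1, c(1, 2)), class = "hfa_insufficient_data_error")
})

test_that("assumption gate transforms skewed data and flags degeneracy", {
  set.seed(51)
  x <- rlnorm(60, 0, 1.5)
  g <- rep(c("a", "b"), each = 30)
  res <- assumption_gate(x, g)
  expect_lt(res$normality_p, 0.05)
  expect_true(res$transformed)
  expect_gt(res$normality_p_after, res$normality_p)

  ok <- assumption_gate(rnorm(60), g)
  expect_false(ok$transformed)

  cst <- assumption_gate(rep(1, 10), rep(c("a", "b"), 5))
  expect_true(cst$degenerate)
  expect_false(cst$transformed)

  expect_error(assumption_gate(c(1, 2), c("a", "b")),
               class = "hfa_insufficient_data_error")
})

test_that("simple linkage recovers exact linear relationships", {
  x <- 1:10
  suppressWarnings(res <- simple_linkage(2 * x, x))  # exact fit warns in summary.lm
  expect_equal(unname(res$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(res$r_squared, 1)
  expect_error(simple_linkage(rnorm(5), rep(1, 5)),
               class = "hfa_degenerate_predictor_error")
  expect_error(simple_linkage(1:2, 1:2),
               class = "hfa_insufficient_data_error")
})

test_that("multi-taxon regression flags the truly predictive taxon", {
  set.seed(61)
  hits <- 0L
  for (r in 1:60) {
    X <- as.data.frame(matrix(runif(32 * 8, 0, 2), 32, 8))
    names(X) <- paste0("class", 1:8)
    y <- 8 * X$class3 + rnorm(32, 0, 1.5)
    res <- multi_taxon_linkage(y, X)
    if ("class3" %in% res$flagged) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)

  # flagged taxa get a simple refit
  X <- as.data.frame(matrix(runif(40 * 3), 40, 3))
  names(X) <- c("u", "v", "w")
  y <- 5 * X$u + rnorm(40, 0, 0.2)
  res <- multi_taxon_linkage(y, X)
  expect_true("u" %in% res$flagged)
  expect_s3_class(res$refits$u, "hfa_linkage")
  expect_gt(res$refits$u$r_squared, 0.8)

  # boundary: as many coefficients as observations fits with a warning
  X9 <- as.data.frame(matrix(rnorm(9 * 8), 9, 8))
  expect_warning(multi_taxon_linkage(rnorm(9), X9), "degrees of freedom")

  # all-noise predictors rarely get flagged
  set.seed(62)
  flags <- vapply(1:100, function(r) {
    X <- as.data.frame(matrix(rnorm(30 * 8), 30, 8))
    length(multi_taxon_linkage(rnorm(30), X)$flagged)
  }, numeric(1))
  expect_lt(mean(flags), 1.0)  # expectation is 8 x 0.05 = 0.4
})
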