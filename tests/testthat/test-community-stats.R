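uniform_table <- tibble::tibble(feature_id = paste0("f", 1:4),
                                s1 = c(5, 5, 5, 5))

test_that("alpha diversity matches closed forms", {
  expect_equal(alpha_diversity(uniform_table, "observed")$value, 4)
  expect_equal(alpha_diversity(uniform_table, "shannon")$value, log(4),
               tolerance = 1e-12)
  expect_equal(alpha_diversity(uniform_table, "simpson")$value, 0.75)

  chao_tab <- tibble::tibble(feature_id = paste0("f", 1:5),
                             s1 = c(1, 1, 2, 2, 3))
  expect_equal(alpha_diversity(chao_tab, "chao1")$value, 5 + 4 / 4)

  # no singletons: chao1 equals observed
  no_single <- tibble::tibble(feature_id = paste0("f", 1:3),
                              s1 = c(2, 3, 4))
  expect_equal(alpha_diversity(no_single, "chao1")$value, 3)

  empty <- tibble::tibble(feature_id = "f1", s1 = 0)
  expect_warning(out <- alpha_diversity(empty, "shannon"), "no detected")
  expect_equal(out$value, 0)
})

test_that("ACE agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(2, {
    x <- rpois(40, 3)
  })
  tab <- tibble::tibble(feature_id = paste0("f", seq_along(x)), s1 = x)
  expect_equal(alpha_diversity(tab, "ace")$value,
               unname(vegan::estimateR(x)["S.ACE"]), tolerance = 1e-8)
})

test_that("Bray-Curtis matches hand values and the vegan oracle", {
  tab <- tibble::tibble(feature_id = c("a", "b"),
                        s1 = c(1, 1), s2 = c(1, 3), s3 = c(1, 1),
                        s4 = c(0, 5))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s1", "s3"], 0)
  disjoint <- tibble::tibble(feature_id = c("a", "b"),
                             s1 = c(2, 0), s2 = c(0, 7))
  expect_equal(as.matrix(bray_curtis(disjoint))["s1", "s2"], 1)

  skip_if_not_installed("vegan")
  withr::with_seed(9, {
    m <- matrix(rpois(60, 8), nrow = 10)
  })
  tab2 <- tibble::tibble(feature_id = paste0("f", 1:10),
                         !!!as.data.frame(m) |> setNames(paste0("s", 1:6)))
  expect_equal(as.matrix(bray_curtis(tab2)),
               as.matrix(vegan::vegdist(t(m))) |>
                 `dimnames<-`(list(paste0("s", 1:6), paste0("s", 1:6))),
               tolerance = 1e-12)
})

test_that("PCoA solves small cases and recovers Euclidean configurations", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  out <- pcoa(d2)
  expect_equal(sort(abs(out$coordinates$Axis1)), c(0.5, 0.5))

  withr::with_seed(4, {
    pts <- matrix(rnorm(24), nrow = 8)
  })
  rownames(pts) <- paste0("s", 1:8)
  d <- stats::dist(pts)
  rec <- pcoa(d)
  coords <- as.matrix(rec$coordinates[-1])
  expect_equal(as.matrix(stats::dist(coords)),
               as.matrix(d), tolerance = 1e-8,
               ignore_attr = TRUE)

  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  eq <- pcoa(d3)
  expect_equal(length(eq$eigenvalues), 2)
  expect_equal(eq$eigenvalues[1], eq$eigenvalues[2], tolerance = 1e-10)

  zero <- pcoa(matrix(0, 3, 3))
  expect_true(all(zero$coordinates$Axis1 == 0))
})

test_that("PERMANOVA matches the vegan oracle and is seed-deterministic", {
  skip_if_not_installed("vegan")
  withr::with_seed(3, {
    m <- matrix(rpois(80, 10), nrow = 10)
  })
  tab <- tibble::tibble(feature_id = paste0("f", 1:10),
                        !!!as.data.frame(m) |> setNames(paste0("s", 1:8)))
  d <- bray_curtis(tab)
  lab <- rep(c("a", "b"), each = 4)
  pm <- permanova(d, lab, n_perm = 199, seed = 7)
  ad <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ g,
                       data = data.frame(g = lab), permutations = 199)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)

  pm2 <- permanova(d, lab, n_perm = 199, seed = 7)
  expect_identical(pm$p_value, pm2$p_value)
  expect_error(permanova(d, rep("a", 8)), "2 groups")
})

test_that("exhaustive PERMANOVA enumerates the 35 bipartitions of 4+4", {
  # strongly separated groups: observed F is the maximum over bipartitions
  withr::with_seed(21, {
    ma <- matrix(rpois(24, 50), nrow = 6)   # group a: features 1-3 high
    ma[4:6, ] <- rpois(12, 1)
    mb <- matrix(rpois(24, 50), nrow = 6)   # group b: features 4-6 high
    mb[1:3, ] <- rpois(12, 1)
  })
  tab <- tibble::tibble(feature_id = paste0("f", 1:6),
                        !!!as.data.frame(cbind(ma, mb)) |>
                          setNames(paste0("s", 1:8)))
  d <- bray_curtis(tab)
  lab <- rep(c("a", "b"), each = 4)
  pm <- permanova(d, lab, exhaustive = TRUE)
  expect_equal(pm$n_perm, 35)
  expect_equal(pm$p_value, 1 / 35, tolerance = 1e-12)

  # brute-force oracle: recompute every bipartition's F independently
  skip_if_not_installed("vegan")
  combos <- utils::combn(2:8, 3, simplify = FALSE)
  fs <- vapply(combos, function(idx) {
    g <- rep("b", 8)
    g[c(1, idx)] <- "a"
    vegan::adonis2(stats::as.dist(as.matrix(d)) ~ g,
                   data = data.frame(g = g), permutations = 1)$F[1]
  }, numeric(1))
  expect_equal(sum(fs >= pm$statistic - 1e-12) / 35, pm$p_value)
})

test_that("Procrustes is invariant to rotation/scaling and matches protest", {
  withr::with_seed(5, {
    x <- matrix(rnorm(16), nrow = 8)
  })
  rownames(x) <- paste0("s", 1:8)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y <- 3 * x %*% rot
  pr <- procrustes_test(x, y, n_perm = 99, seed = 1)
  expect_equal(pr$m2, 0, tolerance = 1e-10)
  expect_equal(pr$r, 1, tolerance = 1e-10)

  # relabeling symmetry: permuting both rows identically leaves m2 unchanged
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  pr2 <- procrustes_test(x[perm, ], y[perm, ], n_perm = 99, seed = 1)
  expect_equal(pr2$m2, pr$m2, tolerance = 1e-12)

  skip_if_not_installed("vegan")
  withr::with_seed(6, {
    z <- matrix(rnorm(16), nrow = 8)
  })
  rownames(z) <- paste0("s", 1:8)
  pr3 <- procrustes_test(x, z, n_perm = 99, seed = 1)
  pv <- vegan::protest(x, z, permutations = 99)
  expect_equal(pr3$m2, pv$ss, tolerance = 1e-10)
  expect_equal(pr3$r, pv$t0, tolerance = 1e-10)

  expect_error(procrustes_test(x, z[c(8:1), ][1:7, ], n_perm = 9),
               "match")
})

test_that("independent configurations rarely yield small Procrustes p", {
  hits <- 0
  for (i in 1:100) {
    withr::with_seed(1000 + i, {
      x <- matrix(rnorm(16), nrow = 8)
      y <- matrix(rnorm(16), nrow = 8)
    })
    rownames(x) <- rownames(y) <- paste0("s", 1:8)
    pr <- procrustes_test(x, y, n_perm = 99, seed = i)
    hits <- hits + (pr$p_value <= 0.05)
  }
  expect_lte(hits, 10)  # p > 0.05 in at least 90% of null replicates
})

test_that("group comparison gates between parametric and rank tests", {
  # identical groups: rank branch, p = 1
  same <- group_compare(rep(c(1, 1, 1, 1), 2), rep(c("a", "b"), each = 4))
  expect_equal(same$p_value, 1)

  # clearly skewed data selects the Wilcoxon branch
  withr::with_seed(11, {
    skewed <- exp(rnorm(16, 0, 2))
  })
  gc1 <- group_compare(skewed, rep(c("a", "b"), each = 8))
  expect_equal(gc1$method, "wilcoxon")

  # complete separation at 4 vs 4 with a gross outlier: the rank branch is
  # taken and the exact two-sided Wilcoxon p is 2/70
  sep <- group_compare(c(1, 2, 3, 4, 5, 6, 7, 1e6),
                       rep(c("a", "b"), each = 4))
  expect_equal(sep$method, "wilcoxon")
  expect_equal(sep$p_value, 2 / 70, tolerance = 1e-12)

  # near-normal homoscedastic data selects the t-test
  withr::with_seed(12, {
    normal <- rnorm(20)
  })
  gc2 <- group_compare(normal, rep(c("a", "b"), each = 10))
  expect_equal(gc2$method, "t-test")

  # multi-group skewed data: Kruskal-Wallis with Dunn post hoc
  withr::with_seed(13, {
    multi <- exp(rnorm(30, 0, 2))
  })
  gc3 <- group_compare(multi, rep(c("a", "b", "c"), each = 10))
  expect_equal(gc3$method, "kruskal-wallis")
  expect_s3_class(gc3$posthoc, "tbl_df")
  expect_equal(nrow(gc3$posthoc), 3)

  expect_error(group_compare(1:3, c("a", "a", "b")), "at least 2")
})

test_that("batch correlations apply BH across the batch and flag degeneracy", {
  x <- 1:10
  pairs <- dplyr::bind_rows(
    tibble::tibble(pair = "same", x = x, y = x),
    tibble::tibble(pair = "anti", x = x, y = -x),
    tibble::tibble(pair = "flat", x = x, y = rep(1, 10))
  )
  out <- correlate_fdr(pairs, method = "pearson")
  expect_equal(out$estimate[out$pair == "same"], 1)
  expect_equal(out$estimate[out$pair == "anti"], -1)
  expect_true(out$flagged[out$pair == "flat"])
  expect_true(is.na(out$estimate[out$pair == "flat"]))

  # identical evidence in every pair: BH leaves the p-values unchanged
  withr::with_seed(14, {
    xr <- rnorm(12)
  })
  batch <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(pair = paste0("p", i), x = xr, y = xr * 2 + 1)
  })
  res <- correlate_fdr(batch)
  expect_true(all(abs(res$q_value - res$p_value) < 1e-12))
})
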