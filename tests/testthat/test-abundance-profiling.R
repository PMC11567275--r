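test_that("presence thresholds match the published rules", {
  # viral: >=70% breadth OR >= 5,000 bp covered
  expect_true(call_presence(cov_row("v", "s", 40000, 5000, 1), "viral")$present)
  expect_true(call_presence(cov_row("v", "s", 4000, 2900, 1), "viral")$present)
  expect_false(call_presence(cov_row("v", "s", 40000, 4999, 1),
                             "viral")$present)
  expect_true(call_presence(cov_row("v", "s", 1000, 700, 1),
                            "viral")$present)    # breadth exactly 0.70
  # bacterial: >=70% breadth OR >= 100,000 bp covered
  expect_false(call_presence(cov_row("b", "s", 2e6, 99999, 1),
                             "bacterial")$present)
  expect_true(call_presence(cov_row("b", "s", 2e6, 100000, 1),
                            "bacterial")$present)
  expect_error(call_presence(cov_row("x", "s", 100, 10, 1), "gene"),
               "unknown")
})

test_that("presence is monotone in covered bases", {
  for (cov in seq(0, 40000, by = 2500)) {
    lo <- call_presence(cov_row("v", "s", 40000, cov, 1), "viral")$present
    hi <- call_presence(cov_row("v", "s", 40000, min(cov + 2500, 40000), 1),
                        "viral")$present
    expect_true(hi >= lo)
  }
})

test_that("feature tables apply prevalence and half-up rounding", {
  recs <- dplyr::bind_rows(
    cov_row("kept", paste0("s", 1:4), 4000, 3500, 2.5),
    cov_row("rare", paste0("s", 1:2), 4000, 3500, 9),
    cov_row("rare", paste0("s", 3:4), 4000, 100, 9)  # present in only 2
  )
  tab <- build_feature_table(recs, "viral", min_samples = 3)
  expect_equal(tab$feature_id, "kept")
  expect_equal(unlist(tab[1, -1], use.names = FALSE), rep(3, 4))  # 2.5 -> 3

  dup <- dplyr::bind_rows(cov_row("a", "s1", 100, 90, 1),
                          cov_row("a", "s1", 100, 80, 1))
  expect_error(build_feature_table(dup, "viral"), "duplicate")

  none <- cov_row("a", paste0("s", 1:4), 40000, 0, 0)
  expect_equal(nrow(build_feature_table(none, "viral")), 0)
})

test_that("feature table matches the brute-force per-cell construction", {
  withr::with_seed(42, {
    feats <- paste0("f", 1:8)
    samps <- paste0("s", 1:6)
    grid <- expand.grid(feature_id = feats, sample_id = samps,
                        stringsAsFactors = FALSE)
    grid$length <- 10000
    grid$covered_bases <- sample(0:10000, nrow(grid), replace = TRUE)
    grid$breadth <- grid$covered_bases / grid$length
    grid$mean_depth <- stats::runif(nrow(grid), 0, 20)
    grid$assay <- "bulk"
    recs <- tibble::as_tibble(grid)
  })
  tab <- build_feature_table(recs, "viral", min_samples = 3)

  # oracle: per-cell rule applied with explicit loops
  present <- function(r) r$breadth >= 0.70 || r$covered_bases >= 5000
  expected <- matrix(0, length(unique(recs$feature_id)),
                     length(unique(recs$sample_id)),
                     dimnames = list(sort(unique(recs$feature_id)),
                                     sort(unique(recs$sample_id))))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    expected[r$feature_id, r$sample_id] <-
      if (present(r)) sign(r$mean_depth) * floor(abs(r$mean_depth) + 0.5)
      else 0
  }
  keep <- rowSums(sapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    out <- rep(FALSE, nrow(expected))
    names(out) <- rownames(expected)
    out[r$feature_id] <- present(r)
    out
  })) >= 3
  expected <- expected[keep, , drop = FALSE]
  got <- as.matrix(tab[-1])
  rownames(got) <- tab$feature_id
  expect_equal(got, expected[rownames(got), , drop = FALSE])
})

test_that("relative tables normalise columns and flag empty samples", {
  tab <- tibble::tibble(feature_id = c("a", "b"),
                        s1 = c(2, 2), s2 = c(0, 0), s3 = c(1, 3))
  rel <- to_relative(tab)
  expect_equal(rel$s1, c(0.5, 0.5))
  expect_equal(rel$s2, c(0, 0))
  expect_equal(sum(rel$s3), 1, tolerance = 1e-12)
  expect_equal(attr(rel, "zero_samples"), "s2")
})

test_that("lifestyle totals partition the viral composition", {
  tab <- tibble::tibble(feature_id = c("t1", "t2", "v1"),
                        s1 = c(4, 4, 2), s2 = c(1, 0, 9))
  catalog <- tibble::tibble(srg_id = c("t1", "t2", "v1"),
                            lifestyle = c("temperate", "temperate",
                                          "virulent"))
  lt <- lifestyle_totals(to_relative(tab), catalog)
  s1 <- lt[lt$sample_id == "s1", ]
  expect_equal(s1$total[s1$lifestyle == "temperate"], 0.8)
  expect_equal(s1$total[s1$lifestyle == "virulent"], 0.2)

  all_temp <- lifestyle_totals(
    to_relative(tab[1:2, ]),
    catalog[1:2, ])
  expect_equal(all_temp$total[all_temp$lifestyle == "temperate"], c(1, 1))
  expect_equal(all_temp$total[all_temp$lifestyle == "virulent"], c(0, 0))

  expect_error(lifestyle_totals(to_relative(tab), catalog[1:2, ]), "missing")
})

test_that("gene profiling uses the strict breadth rule and sums by gene id", {
  ann <- tibble::tibble(orf_id = c("o1", "o2", "o3"),
                        gene_id = c("K01034", "K01034", "K99999"))
  recs <- dplyr::bind_rows(
    cov_row("o1", paste0("s", 1:3), 1000, 800, 3.0),
    cov_row("o2", paste0("s", 1:3), 1000, 900, 4.0),
    cov_row("o3", paste0("s", 1:3), 1000, 700, 50)   # breadth exactly 0.70
  )
  tab <- profile_genes(recs, ann, min_samples = 3)
  expect_equal(tab$feature_id, "K01034")
  expect_equal(unlist(tab[1, -1], use.names = FALSE), rep(7, 3))

  empty <- profile_genes(recs[recs$breadth <= 0.70, ], ann)
  expect_equal(nrow(empty), 0)
})

test_that("SCFA totals honour multi-group membership", {
  groups <- scfa_gene_groups()
  expect_true(all(c("K01895", "K01913", "K00925") %in%
                    c(groups$acetate, groups$butyrate, groups$propionate)))

  tab <- tibble::tibble(feature_id = c("K00634", "K01895", "K99999"),
                        s1 = c(0.2, 0.1, 0.7))
  tot <- scfa_totals(tab)
  expect_equal(tot$total[tot$scfa == "butyrate"], 0.2)
  expect_equal(tot$total[tot$scfa == "acetate"], 0.1)
  expect_equal(tot$total[tot$scfa == "propionate"], 0.1)

  empty <- scfa_totals(tab[0, ])
  expect_true(all(empty$total == 0) || nrow(empty) == 0)
})

test_that("planted prophages appear in bulk but not in clean VLP tables", {
  cfg <- community_config(induction_rate = 0, vlp_contamination = 0)
  sim <- simulate_experiment(cfg, seed = 6)
  gt <- sim$ground_truth
  temp_ids <- gt$phages$phage_id[gt$phages$lifestyle_true == "temperate"]
  bulk <- build_feature_table(
    dplyr::filter(sim$coverage, assay == "bulk", feature_id %in% temp_ids),
    "viral")
  vlp_cov <- dplyr::filter(sim$coverage, assay == "vlp",
                           feature_id %in% temp_ids)
  expect_gt(nrow(bulk), 0)
  expect_true(all(call_presence(vlp_cov, "viral")$present == FALSE))
})
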