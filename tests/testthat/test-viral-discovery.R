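test_that("completeness filter applies the documented boundaries", {
  contigs <- dplyr::bind_rows(
    contig_row("exact50", completeness = 50.0, contamination = 0),
    contig_row("just_below", completeness = 49.9, contamination = 0),
    contig_row("contaminated", completeness = 90, contamination = 10.0),
    contig_row("clean", completeness = 90, contamination = 9.9)
  )
  kept <- filter_completeness(contigs)
  expect_equal(kept$contig_id, c("exact50", "clean"))

  contigs$completeness_pct[2] <- NA
  expect_error(filter_completeness(contigs), "just_below")
})

test_that("dereplication clusters identical and contained sequences", {
  s40 <- random_seq(40000, seed = 1)
  s5 <- substr(s40, 10001, 15000)        # exactly contained
  s10a <- random_seq(10000, seed = 2)
  s10b <- random_seq(10000, seed = 3)    # unrelated

  contigs <- dplyr::bind_rows(
    contig_row("big", length = 40000, sequence = s40),
    contig_row("contained", length = 5000, sequence = s5),
    contig_row("loner_a", length = 10000, sequence = s10a),
    contig_row("loner_b", length = 10000, sequence = s10b),
    contig_row("twin", length = 10000, sequence = s10a)
  )
  out <- dereplicate(contigs)
  expect_setequal(out$representatives$contig_id, c("big", "loner_a",
                                                   "loner_b"))
  cl <- out$clusters
  expect_equal(cl$representative_id[cl$contig_id == "contained"], "big")
  # equal-length tie resolved lexicographically: loner_a represents twin
  expect_equal(cl$representative_id[cl$contig_id == "twin"], "loner_a")

  # idempotence
  again <- dereplicate(out$representatives)
  expect_identical(sort(again$representatives$contig_id),
                   sort(out$representatives$contig_id))
})

test_that("dereplication identity threshold agrees with the alignment oracle", {
  skip_if_not_installed("Biostrings")
  target <- random_seq(20000, seed = 10)
  near <- mutate_seq(substr(target, 3001, 8000), 0.005, seed = 11)  # 99.5% id
  far <- mutate_seq(substr(target, 3001, 8000), 0.05, seed = 12)    # 95% id

  oracle_pid <- function(q, t) {
    aln <- Biostrings::pairwiseAlignment(q, t, type = "global-local")
    Biostrings::pid(aln)
  }
  expect_gte(oracle_pid(near, target), 99)
  expect_lt(oracle_pid(far, target), 99)

  contigs <- dplyr::bind_rows(
    contig_row("target", length = 20000, sequence = target),
    contig_row("near", length = 5000, sequence = near),
    contig_row("far", length = 5000, sequence = far)
  )
  out <- dereplicate(contigs)
  cl <- out$clusters
  expect_equal(cl$representative_id[cl$contig_id == "near"], "target")
  expect_equal(cl$representative_id[cl$contig_id == "far"], "far")
})

test_that("empty input dereplicates to empty output", {
  out <- dereplicate(contig_row("x")[0, ])
  expect_equal(nrow(out$representatives), 0)
  expect_equal(nrow(out$clusters), 0)
})

test_that("viral validation implements the predictor/structural/ORF cascade", {
  contigs <- dplyr::bind_rows(
    contig_row("ok"),
    contig_row("no_struct"),
    contig_row("single_big"),
    contig_row("unpredicted", virsorter = FALSE, vibrant = FALSE),
    contig_row("single_small")
  )
  genes <- dplyr::bind_rows(
    gene_rows("ok", n_structural = 3),
    gene_rows("no_struct", n_structural = 0),
    gene_rows("single_big", n_structural = 1, n_other = 150),
    gene_rows("unpredicted", n_structural = 3),
    gene_rows("single_small", n_structural = 1, n_other = 10)
  )
  v <- validate_viral(contigs, genes)
  expect_equal(v$verdict,
               c("pass", "fail", "fail", "fail", "pass"))
  expect_equal(v$reason,
               c(NA, "no_structural", "single_structural_large",
                 "no_predictor", NA))
})

test_that("validation is a pure per-contig function (order independent)", {
  contigs <- dplyr::bind_rows(
    contig_row("a"), contig_row("b", virsorter = FALSE, vibrant = FALSE),
    contig_row("c")
  )
  genes <- dplyr::bind_rows(gene_rows("a"), gene_rows("b"),
                            gene_rows("c", n_structural = 0))
  fwd <- validate_viral(contigs, genes)
  rev <- validate_viral(contigs[3:1, ], genes)
  expect_equal(dplyr::arrange(fwd, contig_id), dplyr::arrange(rev, contig_id))
})

test_that("lifestyle classification follows lysogeny markers or host evidence", {
  contigs <- dplyr::bind_rows(
    contig_row("with_integrase"),
    contig_row("host_flanked", host_evidence = TRUE),
    contig_row("bare")
  )
  genes <- dplyr::bind_rows(
    gene_rows("with_integrase", markers = "integrase"),
    gene_rows("host_flanked"),
    gene_rows("bare")
  )
  cl <- classify_lifestyle(contigs, genes)
  expect_equal(cl$lifestyle, c("temperate", "temperate", "virulent"))
})

test_that("the catalog partitions validated contigs by lifestyle", {
  gt <- build_community(community_config(), seed = 5)
  inputs <- emit_catalog_inputs(gt, sequences = "none")
  catalog <- build_viral_catalog(inputs$contigs, inputs$genes)
  smry <- summarize_catalog(catalog)
  expect_equal(smry$temperate + smry$virulent, smry$total)

  # annotation-faithful classification recovers the planted lifestyles
  truth <- setNames(gt$phages$lifestyle_true, gt$phages$phage_id)
  got <- setNames(catalog$lifestyle, catalog$srg_id)
  common <- intersect(names(truth), names(got))
  expect_gt(length(common), 0)
  expect_equal(unname(got[common]), unname(truth[common]))
})

test_that("an empty input yields an empty catalog", {
  catalog <- build_viral_catalog(contig_row("x")[0, ], gene_rows("x")[0, ])
  expect_equal(nrow(catalog), 0)
  expect_equal(summarize_catalog(catalog)$total, 0)
})
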