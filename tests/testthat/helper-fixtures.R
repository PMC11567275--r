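# Shared fixture builders. All fixtures are constructed in code.

# A single annotated contig row.
contig_row <- function(id, length = 40000, completeness = 90,
                       contamination = 0, virsorter = TRUE, vibrant = TRUE,
                       host_evidence = FALSE, host_id = NA_character_,
                       family = NA_character_, sequence = NA_character_) {
  tibble::tibble(
    contig_id = id, length = length, source = "vlp",
    completeness_pct = completeness, contamination_pct = contamination,
    virsorter_like = virsorter, vibrant_like = vibrant,
    host_homology_evidence = host_evidence, host_id = host_id,
    family = family, sequence = sequence
  )
}

# Gene rows for a contig: n_structural structural genes, markers from the
# lysogeny vocabulary, n_other filler ORFs.
gene_rows <- function(contig_id, n_structural = 2, markers = character(0),
                      n_other = 3, metabolic = character(0)) {
  labels <- c(rep("capsid", n_structural), markers, metabolic,
              rep("none", n_other))
  categories <- c(rep("structural", n_structural),
                  rep("lysogeny_marker", length(markers)),
                  rep("metabolic", length(metabolic)),
                  rep("other", n_other))
  k <- length(labels)
  tibble::tibble(
    contig_id = contig_id,
    gene_id = sprintf("%s_g%02d", contig_id, seq_len(k)),
    start = (seq_len(k) - 1) * 1000 + 1,
    end = (seq_len(k) - 1) * 1000 + 900,
    strand = "+",
    category = categories,
    label = labels
  )
}

# One coverage record.
cov_row <- function(feature_id, sample_id, length, covered, depth,
                    assay = "bulk") {
  tibble::tibble(
    feature_id = feature_id, sample_id = sample_id, assay = assay,
    length = length, covered_bases = covered, breadth = covered / length,
    mean_depth = depth
  )
}

# The published catalog's bookkeeping fixture: 480 family-assigned contigs
# carrying lysogeny markers, 100 unassigned contigs carrying lysogeny
# markers, and 236 contigs with neither markers nor host evidence.
catalog_816_fixture <- function() {
  ids_fam <- sprintf("fam_%03d", 1:480)
  ids_unk <- sprintf("unk_%03d", 1:100)
  ids_vir <- sprintf("vir_%03d", 1:236)
  contigs <- dplyr::bind_rows(
    purrr::map_dfr(ids_fam, contig_row, family = "known_family"),
    purrr::map_dfr(ids_unk, contig_row),
    purrr::map_dfr(ids_vir, contig_row)
  )
  genes <- dplyr::bind_rows(
    purrr::map_dfr(ids_fam, gene_rows, markers = "integrase"),
    purrr::map_dfr(ids_unk, gene_rows, markers = "transposase"),
    purrr::map_dfr(ids_vir, gene_rows)
  )
  list(contigs = contigs, genes = genes)
}

random_seq <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Point-mutate a fraction of positions (substitutions only, so planted
# identity is exact).
mutate_seq <- function(s, rate, seed) {
  withr::with_seed(seed, {
    chars <- strsplit(s, "")[[1]]
    idx <- sample(length(chars), round(rate * length(chars)))
    for (i in idx) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    paste(chars, collapse = "")
  })
}

# Small two-group lognormal count matrix for engine calibration tests.
null_counts <- function(n_features = 30, n_per_group = 4, seed = 1,
                        sdlog = 0.6, mean_depth = 200) {
  withr::with_seed(seed, {
    m <- matrix(round(rlnorm(n_features * 2 * n_per_group,
                             log(mean_depth), sdlog)),
                nrow = n_features)
    rownames(m) <- sprintf("f%03d", seq_len(n_features))
    colnames(m) <- sprintf("s%02d", seq_len(2 * n_per_group))
    m
  })
}

null_labels <- function(n_per_group = 4) rep(c("a", "b"), each = n_per_group)
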