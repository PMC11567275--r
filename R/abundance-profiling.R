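#' Breadth-of-coverage presence call
#'
#' A viral SRG counts as detected in a sample when at least 70% of its
#' length or at least 5,000 bp is covered; a bacterial SRG when at least 70%
#' or at least 100,000 bp is covered. Both cutoffs are inclusive (`>=`).
#'
#' @param records coverage tibble (`feature_id`, `sample_id`, `length`,
#'   `covered_bases`, `breadth`, ...).
#' @param kind `"viral"` or `"bacterial"`.
#' @param min_breadth breadth cutoff (default 0.70).
#' @return `records` with a logical `present` column appended.
#' @export
#' @examples
#' rec <- tibble::tibble(feature_id = "v1", sample_id = "s1",
#'                       length = 40000, covered_bases = 5000,
#'                       breadth = 0.125, mean_depth = 0.2)
#' call_presence(rec, "viral")$present  # TRUE: 5,000 bp covered
call_presence <- function(records, kind, min_breadth = 0.70) {
  assert_columns(records, c("length", "covered_bases", "breadth"))
  min_bases <- switch(kind,
                      viral = 5000,
                      bacterial = 100000,
                      abort(sprintf("unknown presence kind: '%s'", kind)))
  mutate(records,
         present = .data$breadth >= min_breadth |
           .data$covered_bases >= min_bases)
}

#' Build an integer feature table from coverage records
#'
#' Applies the presence call, takes raw abundance as the rounded (half away
#' from zero) mean depth where present and 0 elsewhere, and keeps features
#' detected in at least `min_samples` samples ("more than 2" in the default
#' profiling workflow, applied within one assay).
#'
#' @param records coverage tibble for a single assay.
#' @param kind `"viral"` or `"bacterial"` (gene tables are built by
#'   [profile_genes()], which uses the strict gene detection rule).
#' @param min_samples prevalence filter (default 3).
#' @return A wide tibble of class `virome_feature_table`: `feature_id`
#'   column plus one integer column per sample (columns ordered by
#'   `sample_id`, rows by `feature_id`).
#' @export
build_feature_table <- function(records, kind, min_samples = 3) {
  assert_columns(records, c("feature_id", "sample_id", "length",
                            "covered_bases", "breadth", "mean_depth"))
  dup <- records |>
    dplyr::count(.data$feature_id, .data$sample_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate coverage records for: %s",
                  paste(paste(dup$feature_id, dup$sample_id, sep = "/"),
                        collapse = ", ")))
  }
  called <- call_presence(records, kind)
  called <- mutate(called,
                   abundance = if_else(.data$present,
                                       round_half_up(.data$mean_depth), 0))
  prevalent <- called |>
    group_by(.data$feature_id) |>
    summarise(n_detected = sum(.data$present), .groups = "drop") |>
    filter(.data$n_detected >= min_samples) |>
    pull("feature_id")
  wide <- called |>
    filter(.data$feature_id %in% prevalent) |>
    select("feature_id", "sample_id", "abundance") |>
    arrange(.data$feature_id, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance",
                       values_fill = 0, names_sort = TRUE)
  structure(wide, class = c("virome_feature_table", class(wide)),
            kind = kind, min_samples = min_samples)
}

#' Convert a feature table to relative abundances
#'
#' Divides each sample column by its sum; the denominator is the sum over
#' the table's retained features (compositional treatment). All-zero
#' samples stay zero and are flagged in the `zero_samples` attribute.
#'
#' @param table a `virome_feature_table` (or any tibble whose first column
#'   is `feature_id` and remaining columns are counts).
#' @return The table with fractional columns; attribute `zero_samples`
#'   names any all-zero samples.
#' @export
to_relative <- function(table) {
  samples <- setdiff(names(table), "feature_id")
  sums <- vapply(table[samples], sum, numeric(1))
  zero <- samples[sums == 0]
  out <- table
  for (s in samples) {
    if (sums[[s]] > 0) out[[s]] <- out[[s]] / sums[[s]]
  }
  attr(out, "zero_samples") <- zero
  attr(out, "relative") <- TRUE
  out
}

#' Total relative abundance per lifestyle
#'
#' Sums the relative abundances of temperate and of virulent SRGs per
#' sample.
#'
#' @param rel_table a relative viral feature table ([to_relative()]).
#' @param catalog a `viral_catalog` (or tibble with `srg_id`, `lifestyle`).
#' @return A tibble `sample_id`, `lifestyle`, `total`.
#' @export
lifestyle_totals <- function(rel_table, catalog) {
  assert_columns(catalog, c("srg_id", "lifestyle"))
  missing <- setdiff(rel_table$feature_id, catalog$srg_id)
  if (length(missing) > 0) {
    abort(sprintf("feature(s) missing from catalog: %s",
                  paste(missing, collapse = ", ")))
  }
  rel_table |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "rel_abundance") |>
    left_join(select(catalog, "srg_id", "lifestyle"),
              by = c(feature_id = "srg_id")) |>
    group_by(.data$sample_id, .data$lifestyle) |>
    summarise(total = sum(.data$rel_abundance), .groups = "drop") |>
    tidyr::complete(sample_id = unique(.data$sample_id),
                    lifestyle = c("temperate", "virulent"),
                    fill = list(total = 0))
}

#' Profile bacterial genes from ORF coverage
#'
#' An ORF is detected when its length coverage is strictly above
#' `min_breadth` (70% by default); its raw abundance is the mean depth.
#' Abundances of detected ORFs sharing a gene identifier are summed, then
#' integerised (half away from zero).
#'
#' @param orf_records coverage tibble over ORFs (bulk assay).
#' @param annotations tibble mapping `orf_id` to `gene_id`. ORFs without a
#'   mapping are counted under their own id.
#' @param min_breadth strict breadth cutoff for ORF detection.
#' @param min_samples prevalence filter applied to the resulting gene table.
#' @return A gene-level `virome_feature_table`.
#' @export
profile_genes <- function(orf_records, annotations, min_breadth = 0.70,
                          min_samples = 3) {
  assert_columns(orf_records, c("feature_id", "sample_id", "breadth",
                                "mean_depth"))
  assert_columns(annotations, c("orf_id", "gene_id"))
  detected <- filter(orf_records, .data$breadth > min_breadth)
  if (nrow(detected) == 0) {
    empty <- tibble(feature_id = character(0))
    return(structure(empty, class = c("virome_feature_table", class(empty)),
                     kind = "gene", min_samples = min_samples))
  }
  mapped <- detected |>
    left_join(select(annotations, "orf_id", "gene_id"),
              by = c(feature_id = "orf_id")) |>
    mutate(gene_id = dplyr::coalesce(.data$gene_id, .data$feature_id))
  gene_long <- mapped |>
    group_by(feature_id = .data$gene_id, .data$sample_id) |>
    summarise(abundance = round_half_up(sum(.data$mean_depth)),
              .groups = "drop")
  prevalent <- gene_long |>
    group_by(.data$feature_id) |>
    summarise(n_detected = sum(.data$abundance > 0), .groups = "drop") |>
    filter(.data$n_detected >= min_samples) |>
    pull("feature_id")
  all_samples <- sort(unique(orf_records$sample_id))
  wide <- gene_long |>
    filter(.data$feature_id %in% prevalent) |>
    arrange(.data$feature_id, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance",
                       values_fill = 0, names_sort = TRUE)
  for (s in setdiff(all_samples, names(wide))) wide[[s]] <- 0
  wide <- wide[, c("feature_id", all_samples)]
  structure(wide, class = c("virome_feature_table", class(wide)),
            kind = "gene", min_samples = min_samples)
}

#' KEGG orthology groups for short-chain fatty acid synthesis
#'
#' The fixed sets of KEGG gene identifiers associated with acetate,
#' butyrate and propionate production used by [scfa_totals()]. A gene can
#' belong to more than one set (e.g. K01895, K01913, K00925).
#'
#' @return A named list of character vectors.
#' @export
scfa_gene_groups <- function() {
  list(
    acetate = c("K00128", "K00149", "K00138", "K14085", "K00129", "K24012",
                "K01905", "K22224", "K00925", "K19670", "K02576", "K02577",
                "K02578", "K18118", "K01026", "K01067", "K01895", "K01913",
                "K00467", "K00156", "K01512", "K10150", "K01738", "K13034",
                "K17069"),
    butyrate = c("K01034", "K01035", "K19709", "K23756", "K01896", "K01913",
                 "K00929", "K00634"),
    propionate = c("K00925", "K00932", "K19697", "K01895", "K01908",
                   "K20454")
  )
}

#' Cumulative relative abundance of SCFA-synthesis enzymes
#'
#' Sums, per sample, the relative abundances of genes whose KEGG id belongs
#' to each SCFA group; genes in several groups contribute to each.
#'
#' @param rel_gene_table a relative gene table ([to_relative()]).
#' @param groups SCFA gene groups (default [scfa_gene_groups()]).
#' @return A tibble `sample_id`, `scfa`, `total`.
#' @export
scfa_totals <- function(rel_gene_table, groups = scfa_gene_groups()) {
  samples <- setdiff(names(rel_gene_table), "feature_id")
  purrr::imap_dfr(groups, function(kegg_ids, scfa) {
    sub <- rel_gene_table[rel_gene_table$feature_id %in% kegg_ids, samples,
                          drop = FALSE]
    tibble(sample_id = samples, scfa = scfa,
           total = if (nrow(sub) == 0) rep(0, length(samples))
                   else unname(vapply(sub, sum, numeric(1))))
  })
}
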