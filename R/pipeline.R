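#' Summarise a viral catalog
#'
#' Counts temperate and virulent SRGs and reports the family-assigned and
#' AMG-bearing fractions as percentages with one decimal (half-up).
#'
#' @param catalog a `viral_catalog` (or tibble with `lifestyle` and
#'   optionally `family`, `amg_count`).
#' @return A one-row tibble: `total`, `temperate`, `virulent`,
#'   `family_assigned`, `family_assigned_pct`, `amg_bearing`,
#'   `amg_bearing_pct`.
#' @export
#' @examples
#' cat <- tibble::tibble(srg_id = c("a", "b", "c"),
#'                       lifestyle = c("temperate", "temperate", "virulent"),
#'                       family = c("Siphoviridae", NA, "Myoviridae"),
#'                       amg_count = c(1, 0, 0))
#' summarize_catalog(cat)
summarize_catalog <- function(catalog) {
  total <- nrow(catalog)
  if (total == 0) {
    return(tibble(total = 0L, temperate = 0L, virulent = 0L,
                  family_assigned = 0L, family_assigned_pct = 0,
                  amg_bearing = 0L, amg_bearing_pct = 0))
  }
  n_temp <- sum(catalog$lifestyle == "temperate")
  n_vir <- sum(catalog$lifestyle == "virulent")
  fam <- if ("family" %in% names(catalog)) sum(!is.na(catalog$family)) else 0L
  amg <- if ("amg_count" %in% names(catalog)) {
    sum(catalog$amg_count > 0)
  } else 0L
  tibble(
    total = total, temperate = n_temp, virulent = n_vir,
    family_assigned = fam,
    family_assigned_pct = percent_1dp(fam, total),
    amg_bearing = amg,
    amg_bearing_pct = percent_1dp(amg, total)
  )
}

#' Run a full simulated dual-source experiment
#'
#' Chains the pipeline stages on a synthetic community: simulate, build the
#' viral catalog, profile abundances (bacterial and viral, bulk and VLP),
#' compute community statistics (richness comparison, PERMANOVA, Procrustes,
#' lifestyle totals) and, for two-group designs, the consensus differential
#' abundance. Returns a machine-readable report; given the same config and
#' seed the report is identical.
#'
#' @param config a [community_config()].
#' @param seed integer seed.
#' @param outdir optional directory; stage outputs and `report.json` are
#'   written there.
#' @param genes also profile bacterial genes and SCFA totals?
#' @param saturation also run the depth-saturation analysis on mouse 1?
#' @param n_perm permutations for PERMANOVA/Procrustes.
#' @return A list of class `virome_report`.
#' @export
run_experiment <- function(config = community_config(), seed = 1,
                           outdir = NULL, genes = TRUE, saturation = FALSE,
                           n_perm = 9999) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- stage("simulate", simulate_experiment(config, seed, genes = genes))
  gt <- sim$ground_truth
  meta <- sim$metadata

  inputs <- stage("discover", emit_catalog_inputs(gt, sequences = "none"))
  catalog <- stage("discover",
                   build_viral_catalog(inputs$contigs, inputs$genes))
  catalog_summary <- summarize_catalog(catalog)

  bact_ids <- gt$bacteria$species_id
  viral_ids <- catalog$srg_id
  cov <- sim$coverage

  tables <- stage("profile", list(
    bacterial_bulk = build_feature_table(
      filter(cov, .data$assay == "bulk", .data$feature_id %in% bact_ids),
      "bacterial"),
    viral_bulk = build_feature_table(
      filter(cov, .data$assay == "bulk", .data$feature_id %in% viral_ids),
      "viral"),
    viral_vlp = build_feature_table(
      filter(cov, .data$assay == "vlp", .data$feature_id %in% viral_ids),
      "viral")
  ))

  lifestyle <- stage("profile", lapply(
    tables[c("viral_bulk", "viral_vlp")],
    function(tb) lifestyle_totals(to_relative(tb), catalog)))

  stats <- stage("stats", {
    per_table <- lapply(names(tables), function(nm) {
      tb <- tables[[nm]]
      assay_now <- if (grepl("vlp", nm)) "vlp" else "bulk"
      md <- meta |>
        filter(.data$assay == assay_now) |>
        arrange(.data$sample_id)
      samples <- setdiff(names(tb), "feature_id")
      md <- md[match(samples, md$sample_id), ]
      d <- bray_curtis(tb)
      pm <- permanova(d, md$group, n_perm = n_perm,
                      seed = derive_seed(seed, paste0("perm-", nm)))
      rich <- alpha_diversity(tb, "observed")
      cmp <- group_compare(rich$value, md$group)
      list(table = nm,
           permanova = list(F = pm$statistic, R2 = pm$R2, p = pm$p_value),
           richness = list(method = cmp$method, p = cmp$p_value))
    })
    names(per_table) <- names(tables)

    pc_b <- pcoa(bray_curtis(tables$bacterial_bulk))
    pc_v <- pcoa(bray_curtis(tables$viral_bulk))
    pro <- procrustes_test(pc_b, pc_v, n_perm = n_perm,
                           seed = derive_seed(seed, "procrustes"))
    list(per_table = per_table,
         procrustes = list(r = pro$r, m2 = pro$m2, p = pro$p_value))
  })

  da <- stage("da", {
    lapply(tables[c("bacterial_bulk", "viral_bulk")], function(tb) {
      samples <- setdiff(names(tb), "feature_id")
      md <- meta[match(samples, meta$sample_id), ]
      res <- da_consensus(tb, md$group, reference = gt$design$groups[1])
      list(n_consensus = sum(res$consensus),
           consensus_features = sort(res$feature_id[res$consensus]))
    })
  })

  gene_block <- NULL
  if (genes) {
    gene_block <- stage("profile", {
      gtab <- profile_genes(sim$orfs$coverage, sim$orfs$annotations)
      scfa <- scfa_totals(to_relative(gtab))
      list(n_genes = nrow(gtab),
           scfa = tidyr::pivot_wider(scfa, names_from = "scfa",
                                     values_from = "total"))
    })
  }

  sat_block <- NULL
  if (saturation) {
    sat_block <- stage("saturate", {
      grid <- depth_grid()
      depths <- grid$bulk_depths[grid$bulk_depths <=
                                   config$reads_per_sample[["bulk"]]]
      s1 <- meta$sample_id[meta$assay == "bulk"][1]
      recs <- filter(cov, .data$sample_id == s1,
                     .data$feature_id %in% viral_ids)
      curve <- rarefaction_curve(recs, "viral", depths,
                                 native_depth = config$reads_per_sample[["bulk"]],
                                 replicates = grid$replicates,
                                 seed = derive_seed(seed, "rarefaction"))
      plateau <- detect_plateau(curve)
      list(curve = curve, plateau = plateau)
    })
  }

  report <- list(
    config = unclass(config),
    seed = seed,
    input_hash = content_hash(sim$coverage),
    catalog = as.list(catalog_summary),
    filter_counts = as.list(attr(catalog, "filter_counts")),
    lifestyle_totals = lapply(lifestyle, function(x) {
      tidyr::pivot_wider(x, names_from = "lifestyle", values_from = "total")
    }),
    stats = stats,
    differential_abundance = da,
    genes = gene_block,
    saturation = if (!is.null(sat_block)) {
      list(plateau = sat_block$plateau)
    },
    true_da_features = sort(gt$true_da_features)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write_feature_table(tables[[nm]],
                          file.path(outdir, paste0(nm, ".tsv")))
    }
    write_coverage(cov, file.path(outdir, "coverage.tsv"))
    readr::write_tsv(meta, file.path(outdir, "metadata.tsv"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(c(report, list(tables = tables, catalog = catalog, sim = sim)),
            class = "virome_report")
}

# Content hash of an R object (md5 of its serialized bytes).
content_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
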