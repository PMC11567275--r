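#' Configure a synthetic paired bulk/VLP community
#'
#' Builds the parameter list consumed by [build_community()] and
#' [simulate_experiment()]. The defaults emulate a two-arm mouse gut study
#' (4 mice per group) sequenced with paired whole-microbial ("bulk") and
#' viral-like-particle (VLP) shotgun assays: a lognormal bacterial community,
#' temperate phages integrated as prophages that replicate with their hosts
#' and leak into the VLP fraction only at a small induction rate, and free
#' virulent phages whose virions dominate the VLP fraction.
#'
#' @param scenario `"angii"` (default) is the null two-group design (Sham vs
#'   Ang II) with no planted effect; `"fiber"` plants a diet effect (high- vs
#'   low-fiber) on a subset of fiber-degrading bacteria and their prophages,
#'   plus a reverse effect on a few virulent phages.
#' @param n_bacteria,n_temperate,n_virulent species counts. Defaults keep
#'   temperate phages more numerous than virulent ones, as observed in mouse
#'   gut catalogs.
#' @param n_per_group mice per group (the study design uses 4).
#' @param reads_per_sample named paired-end read counts per assay
#'   (`bulk`, `vlp`); defaults are the depths at which recovery saturates.
#' @param read_length read length in bases (paired, so a read pair
#'   contributes `2 * read_length` bases).
#' @param sigma_species sd (natural log) of between-species base abundance.
#' @param sigma_mouse total sd (natural log) of inter-mouse abundance noise.
#'   Inter-mouse variation is hierarchical: a mouse-level scale factor shared
#'   by all taxa (litter/load effects; cancels in relative abundance) plus an
#'   independent per-taxon component; `noise_split` is the fraction of the
#'   total variance carried by the shared factor.
#' @param noise_split fraction of inter-mouse variance that is mouse-shared.
#' @param copy_factor prophage copies per host genome.
#' @param induction_rate fraction of a temperate phage's host abundance that
#'   appears as free virions (hence in the VLP fraction).
#' @param virion_log_mean,virion_log_sd natural-log location/spread of
#'   virulent phage virion abundance, on the host cell-abundance scale.
#' @param vlp_contamination fraction of VLP sequence mass that is residual
#'   bacterial DNA (VLP preps are never perfectly clean).
#' @param effect_log2fc planted log2 fold change (second group vs first) for
#'   differentially abundant features in the `"fiber"` scenario.
#' @param frac_da_bacteria fraction of bacteria planted as fiber responders.
#' @param n_da_virulent number of virulent phages planted with the opposite
#'   effect (enriched under low fiber).
#' @param da_lfc_threshold |log2FC| at or above which a planted feature is
#'   recorded in the ground-truth differential set.
#' @param bact_length_range,phage_length_range genome length ranges (bases).
#' @param genes_per_bacterium metabolic genes drawn per bacterial genome.
#' @param noise logical; `FALSE` switches off all stochastic layers
#'   (inter-mouse noise and binomial coverage noise) for closed-form checks.
#'
#' @return A list of class `community_config`.
#' @export
#' @examples
#' cfg <- community_config(n_bacteria = 5, n_temperate = 8, n_virulent = 3)
#' gt <- build_community(cfg, seed = 1)
community_config <- function(scenario = c("angii", "fiber"),
                             n_bacteria = 30,
                             n_temperate = 60,
                             n_virulent = 25,
                             n_per_group = 4,
                             reads_per_sample = c(bulk = 20e6, vlp = 15e6),
                             read_length = 150,
                             sigma_species = 1.5,
                             sigma_mouse = 0.8,
                             noise_split = 0.75,
                             copy_factor = 1.0,
                             induction_rate = 0.001,
                             virion_log_mean = log(0.3),
                             virion_log_sd = 0.8,
                             vlp_contamination = 0.005,
                             effect_log2fc = 4,
                             frac_da_bacteria = 0.1,
                             n_da_virulent = 3,
                             da_lfc_threshold = 2,
                             bact_length_range = c(2e6, 4e6),
                             phage_length_range = c(3e4, 6e4),
                             genes_per_bacterium = 10,
                             noise = TRUE) {
  scenario <- match.arg(scenario)
  if (n_bacteria < 1 || n_temperate < 0 || n_virulent < 0) {
    abort("species counts must be >= 1 bacterium and >= 0 phages")
  }
  if (n_temperate > 0 && n_virulent > 0) {
    ratio <- n_temperate / n_virulent
    if (!is.finite(ratio) || ratio <= 0) {
      abort("temperate:virulent ratio must be in (0, Inf)")
    }
  }
  if (n_per_group < 2) abort("n_per_group must be >= 2")
  if (any(reads_per_sample <= 0)) abort("reads_per_sample must be positive")
  groups <- if (scenario == "fiber") c("LF", "HF") else c("Sham", "AngII")
  structure(
    list(
      scenario = scenario,
      groups = groups,
      n_bacteria = n_bacteria,
      n_temperate = n_temperate,
      n_virulent = n_virulent,
      n_per_group = n_per_group,
      assays = c("bulk", "vlp"),
      reads_per_sample = reads_per_sample,
      read_length = read_length,
      sigma_species = sigma_species,
      sigma_mouse = sigma_mouse,
      noise_split = noise_split,
      copy_factor = copy_factor,
      induction_rate = induction_rate,
      virion_log_mean = virion_log_mean,
      virion_log_sd = virion_log_sd,
      vlp_contamination = vlp_contamination,
      effect_log2fc = effect_log2fc,
      frac_da_bacteria = frac_da_bacteria,
      n_da_virulent = n_da_virulent,
      da_lfc_threshold = da_lfc_threshold,
      bact_length_range = bact_length_range,
      phage_length_range = phage_length_range,
      genes_per_bacterium = genes_per_bacterium,
      noise = noise
    ),
    class = "community_config"
  )
}

# Controlled vocabularies shared with the annotation layer.
structural_vocabulary <- function() {
  c("terminase", "capsid", "tail", "amidase", "baseplate", "prohead",
    "coat", "virion")
}

lysogeny_vocabulary <- function() {
  c("integrase", "transposase", "recombinase", "cro_ci")
}

phylum_vocabulary <- function() {
  c("Bacillota", "Bacteroidota", "Actinomycetota", "Desulfobacteriota",
    "Pseudomonadota", "Deferribacterota", "Verrucomicrobiota")
}

kegg_vocabulary <- function() {
  unique(c(
    unlist(scfa_gene_groups(), use.names = FALSE),
    sprintf("K%05d", c(1, 2, 36, 45, 90, 101, 161, 240, 370, 401, 500,
                       600, 702, 845, 990, 1100, 1251, 1333, 1440, 1550)),
    c("GH43", "GH13", "GH2", "GH3", "GT2", "GT4", "CE1", "PL1")
  ))
}

#' Build a ground-truth community
#'
#' Draws bacterial species, their integrated prophages (temperate phages) and
#' free virulent phages, plants condition effects according to the scenario,
#' and records which features are truly differentially abundant.
#'
#' @param config a [community_config()].
#' @param seed integer seed; the result is deterministic given
#'   `(config, seed)`.
#' @return A list of class `ground_truth` with tibbles `bacteria` and
#'   `phages`, the `design`, and the character vector `true_da_features`.
#' @export
build_community <- function(config = community_config(), seed = 1) {
  stopifnot(inherits(config, "community_config"))
  if (config$n_temperate > 0 && config$n_bacteria < 1) {
    abort("temperate phages require at least one bacterial host")
  }
  with_seed(derive_seed(seed, "community"), {
    n_b <- config$n_bacteria
    bacteria <- tibble(
      species_id = sprintf("bact_%03d", seq_len(n_b)),
      genome_length = round(stats::runif(n_b, config$bact_length_range[1],
                                         config$bact_length_range[2])),
      phylum_label = sample(phylum_vocabulary(), n_b, replace = TRUE,
                            prob = c(60, 25, 5, 4, 3, 2, 1)),
      base_log_abundance = rnorm(n_b, 0, config$sigma_species),
      effect_log2fc = 0
    )

    # Scenario effects: in the fiber design a subset of bacteria are fiber
    # responders (CAZyme carriers) enriched under high fiber.
    n_da_b <- if (config$scenario == "fiber") {
      max(1L, round(config$frac_da_bacteria * n_b))
    } else 0L
    da_bact <- head(bacteria$species_id, n_da_b)
    bacteria$effect_log2fc[bacteria$species_id %in% da_bact] <-
      config$effect_log2fc

    kegg <- kegg_vocabulary()
    bacteria$gene_complement <- lapply(seq_len(n_b), function(i) {
      genes <- sample(kegg, config$genes_per_bacterium, replace = FALSE)
      if (bacteria$species_id[i] %in% da_bact) {
        # fiber responders carry the arabinan-degrading CAZyme family and
        # acetate/butyrate synthesis genes
        genes <- unique(c("GH43", "K01034", "K00925", genes))
      }
      genes
    })

    n_t <- config$n_temperate
    n_v <- config$n_virulent
    hosts <- if (n_t > 0) {
      # every listed host carries at least one prophage where possible
      c(bacteria$species_id[seq_len(min(n_b, n_t))],
        sample(bacteria$species_id, max(0, n_t - n_b), replace = TRUE))
    } else character(0)

    lys <- lysogeny_vocabulary()
    struct <- structural_vocabulary()
    temperate <- if (n_t > 0) {
      markers <- lapply(seq_len(n_t), function(i) {
        if (stats::runif(1) < 0.1) character(0) else
          sample(lys, sample(1:3, 1))
      })
      tibble(
        phage_id = sprintf("tphage_%03d", seq_len(n_t)),
        genome_length = round(stats::runif(n_t, config$phage_length_range[1],
                                           config$phage_length_range[2])),
        lifestyle_true = "temperate",
        host_id = hosts,
        induction_rate = config$induction_rate,
        virion_abundance_log = NA_real_,
        effect_log2fc = 0,
        structural_genes = lapply(seq_len(n_t),
                                  function(i) sample(struct, sample(2:4, 1))),
        lysogeny_markers = markers,
        host_homology_evidence = vapply(markers, length, 1L) == 0 |
          stats::runif(n_t) < 0.3,
        n_amg = rbinom(n_t, 2, 0.15),
        completeness_pct = stats::runif(n_t, 55, 100),
        contamination_pct = stats::runif(n_t, 0, 8),
        virsorter_like = stats::runif(n_t) < 0.9,
        vibrant_like = stats::runif(n_t) < 0.85
      )
    } else NULL

    virulent <- if (n_v > 0) {
      eff <- rep(0, n_v)
      if (config$scenario == "fiber" && config$n_da_virulent > 0) {
        eff[seq_len(min(config$n_da_virulent, n_v))] <- -config$effect_log2fc
      }
      tibble(
        phage_id = sprintf("vphage_%03d", seq_len(n_v)),
        genome_length = round(stats::runif(n_v, config$phage_length_range[1],
                                           config$phage_length_range[2])),
        lifestyle_true = "virulent",
        host_id = NA_character_,
        induction_rate = NA_real_,
        virion_abundance_log = rnorm(n_v, config$virion_log_mean,
                                     config$virion_log_sd),
        effect_log2fc = eff,
        structural_genes = lapply(seq_len(n_v),
                                  function(i) sample(struct, sample(2:4, 1))),
        lysogeny_markers = replicate(n_v, character(0), simplify = FALSE),
        host_homology_evidence = FALSE,
        n_amg = rbinom(n_v, 2, 0.1),
        completeness_pct = stats::runif(n_v, 55, 100),
        contamination_pct = stats::runif(n_v, 0, 8),
        virsorter_like = stats::runif(n_v) < 0.9,
        vibrant_like = stats::runif(n_v) < 0.85
      )
    } else NULL

    phages <- bind_rows(temperate, virulent)
    # ensure every phage is flagged by at least one predictor
    none <- !phages$virsorter_like & !phages$vibrant_like
    phages$virsorter_like[none] <- TRUE

    # temperate phages inherit their host's planted effect (prophages
    # replicate with the host)
    if (n_t > 0) {
      host_eff <- setNames(bacteria$effect_log2fc, bacteria$species_id)
      idx <- phages$lifestyle_true == "temperate"
      phages$effect_log2fc[idx] <- unname(host_eff[phages$host_id[idx]])
    }

    design <- list(
      groups = config$groups,
      n_per_group = config$n_per_group,
      assays = config$assays,
      reads_per_sample = config$reads_per_sample,
      read_length = config$read_length,
      seed = seed
    )

    all_eff <- c(setNames(bacteria$effect_log2fc, bacteria$species_id),
                 setNames(phages$effect_log2fc, phages$phage_id))
    true_da <- names(all_eff)[abs(all_eff) >= config$da_lfc_threshold]

    structure(
      list(bacteria = bacteria, phages = phages, design = design,
           true_da_features = true_da, config = config),
      class = "ground_truth"
    )
  })
}

#' Simulate per-sample relative abundances for both assays
#'
#' For every mouse, bacterial cell abundances are drawn lognormally around
#' their base abundance plus the planted condition effect; temperate phages
#' track their host (`copy_factor` integrated copies, plus an
#' `induction_rate` fraction released as virions), and virulent phages have
#' free virion abundances. Abundances are converted to sequence-mass
#' fractions (abundance x genome length, normalised per sample and assay),
#' so an integrated prophage attains the same read depth as its host.
#'
#' @param gt a [build_community()] result.
#' @param seed integer seed.
#' @return A tibble with one row per (sample, assay, feature):
#'   `sample_id`, `mouse_id`, `group`, `assay`, `feature_id`, `feature_type`,
#'   `lifestyle`, `cell_abundance`, `rel_abundance`. Each (sample, assay)
#'   block of `rel_abundance` sums to 1.
#' @export
simulate_relative_abundances <- function(gt, seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  cfg <- gt$config
  with_seed(derive_seed(seed, "abundances"), {
    groups <- rep(gt$design$groups, each = gt$design$n_per_group)
    mice <- sprintf("mouse_%02d", seq_along(groups))
    treated <- groups == gt$design$groups[2]
    ln2 <- log(2)
    sigma_total <- if (cfg$noise) cfg$sigma_mouse else 0
    sigma_shared <- sigma_total * sqrt(cfg$noise_split)
    sigma_taxon <- sigma_total * sqrt(1 - cfg$noise_split)

    per_mouse <- purrr::map2(mice, seq_along(mice), function(m, i) {
      mouse_scale <- rnorm(1, 0, sigma_shared)
      b <- gt$bacteria
      a_bact <- exp(b$base_log_abundance +
                      ln2 * b$effect_log2fc * treated[i] +
                      mouse_scale +
                      rnorm(nrow(b), 0, sigma_taxon))
      names(a_bact) <- b$species_id

      p <- gt$phages
      is_temp <- p$lifestyle_true == "temperate"
      host_a <- unname(a_bact[p$host_id])
      a_prophage <- ifelse(is_temp, cfg$copy_factor * host_a, 0)
      a_virion_temp <- ifelse(is_temp, p$induction_rate * host_a, 0)
      a_virion_vir <- ifelse(is_temp, 0,
                             exp(p$virion_abundance_log +
                                   ln2 * p$effect_log2fc * treated[i] +
                                   mouse_scale +
                                   rnorm(nrow(p), 0, sigma_taxon)))

      feat <- tibble(
        feature_id = c(b$species_id, p$phage_id),
        feature_type = c(rep("bacteria", nrow(b)),
                         ifelse(is_temp, "temperate", "virulent")),
        lifestyle = c(rep(NA_character_, nrow(b)), p$lifestyle_true),
        length = c(b$genome_length, p$genome_length),
        cell_bulk = unname(c(a_bact,
                             ifelse(is_temp, a_prophage, a_virion_vir))),
        cell_vlp = c(rep(0, nrow(b)),
                     ifelse(is_temp, a_virion_temp, a_virion_vir))
      )

      mass_bulk <- feat$cell_bulk * feat$length
      rel_bulk <- mass_bulk / sum(mass_bulk)

      mass_vlp_viral <- feat$cell_vlp * feat$length
      mass_bact <- (feat$feature_type == "bacteria") *
        unname(a_bact[feat$feature_id]) * feat$length
      mass_bact[is.na(mass_bact)] <- 0
      viral_sum <- sum(mass_vlp_viral)
      if (viral_sum > 0) {
        rel_vlp <- (1 - cfg$vlp_contamination) * mass_vlp_viral / viral_sum +
          cfg$vlp_contamination * mass_bact / sum(mass_bact)
      } else {
        rel_vlp <- mass_bact / sum(mass_bact)
      }

      bind_rows(
        mutate(feat, assay = "bulk", cell_abundance = .data$cell_bulk,
               rel_abundance = rel_bulk),
        mutate(feat, assay = "vlp", cell_abundance = .data$cell_vlp,
               rel_abundance = rel_vlp)
      ) |>
        mutate(mouse_id = m, group = groups[i],
               sample_id = paste0(m, "_", .data$assay)) |>
        select("sample_id", "mouse_id", "group", "assay", "feature_id",
               "feature_type", "lifestyle", "length", "cell_abundance",
               "rel_abundance")
    })
    dplyr::bind_rows(per_mouse) |>
      filter(.data$assay %in% cfg$assays)
  })
}

#' Convert a relative abundance to a coverage summary
#'
#' Uses the Lander-Waterman expectation: with mean depth
#' `lambda = rel_abundance * total_bases_sequenced / feature_length`, the
#' expected breadth of coverage is `1 - exp(-lambda)`. Covered positions are
#' drawn binomially around that expectation (or set to it exactly when
#' `noise = FALSE`).
#'
#' @param rel_abundance fraction(s) of sequenced bases from the feature.
#' @param total_bases_sequenced total bases sequenced in the sample/assay.
#' @param feature_length feature length(s) in bases.
#' @param seed integer seed (used only when `noise = TRUE`).
#' @param noise draw binomial noise on covered positions?
#' @return A tibble with `length`, `covered_bases`, `breadth`, `mean_depth`.
#' @export
#' @examples
#' abundance_to_coverage(1e-4, 6e9, 40e3, noise = FALSE)
abundance_to_coverage <- function(rel_abundance, total_bases_sequenced,
                                  feature_length, seed = 1, noise = TRUE) {
  if (any(rel_abundance < 0) || any(rel_abundance > 1)) {
    abort("rel_abundance must lie in [0, 1]")
  }
  if (any(total_bases_sequenced < 0) || any(feature_length <= 0)) {
    abort("total_bases_sequenced must be >= 0 and feature_length > 0")
  }
  n <- max(length(rel_abundance), length(feature_length))
  rel <- rep_len(rel_abundance, n)
  len <- rep_len(feature_length, n)
  lambda <- rel * total_bases_sequenced / len
  expected_breadth <- 1 - exp(-lambda)
  covered <- if (noise) {
    with_seed(derive_seed(seed, "coverage"),
              rbinom(n, size = as.integer(len), prob = expected_breadth))
  } else {
    round(expected_breadth * len)
  }
  tibble(
    length = len,
    covered_bases = as.numeric(covered),
    breadth = covered / len,
    mean_depth = lambda
  )
}

#' Simulate coverage summaries for a whole experiment
#'
#' Applies [abundance_to_coverage()] to every (sample, assay, feature) of a
#' simulated abundance table, using the design's per-assay sequencing depth.
#'
#' @param abundances output of [simulate_relative_abundances()].
#' @param design the `design` element of a ground truth.
#' @param seed integer seed.
#' @param noise draw binomial noise on covered positions?
#' @return A coverage tibble with columns `feature_id`, `sample_id`, `assay`,
#'   `length`, `covered_bases`, `breadth`, `mean_depth`.
#' @export
simulate_coverage <- function(abundances, design, seed = 1, noise = TRUE) {
  assert_columns(abundances, c("feature_id", "sample_id", "assay", "length",
                               "rel_abundance"))
  total_bases <- design$reads_per_sample[abundances$assay] * 2 *
    design$read_length
  lambda <- abundances$rel_abundance * total_bases / abundances$length
  expected_breadth <- 1 - exp(-lambda)
  covered <- if (noise) {
    with_seed(derive_seed(seed, "coverage"),
              rbinom(nrow(abundances), size = as.integer(abundances$length),
                     prob = expected_breadth))
  } else {
    round(expected_breadth * abundances$length)
  }
  tibble(
    feature_id = abundances$feature_id,
    sample_id = abundances$sample_id,
    assay = abundances$assay,
    length = abundances$length,
    covered_bases = as.numeric(covered),
    breadth = covered / abundances$length,
    mean_depth = lambda
  )
}

#' Simulate bulk coverage of bacterial gene ORFs
#'
#' Every gene in a bacterium's complement becomes one ORF whose read depth
#' equals its host genome's bulk depth; breadth follows the same
#' Lander-Waterman model at ORF length.
#'
#' @param gt a [build_community()] result.
#' @param abundances output of [simulate_relative_abundances()].
#' @param seed integer seed.
#' @param orf_length ORF length in bases.
#' @param noise draw binomial noise on covered positions?
#' @return A list with `coverage` (ORF coverage tibble, bulk assay) and
#'   `annotations` (tibble `orf_id`, `gene_id`, `species_id`).
#' @export
simulate_gene_coverage <- function(gt, abundances, seed = 1,
                                   orf_length = 1000, noise = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  ann <- purrr::map2_dfr(gt$bacteria$species_id, gt$bacteria$gene_complement,
                         function(sp, genes) {
                           tibble(
                             orf_id = sprintf("%s_orf_%02d", sp,
                                              seq_along(genes)),
                             gene_id = genes,
                             species_id = sp
                           )
                         })
  bulk <- abundances |>
    filter(.data$assay == "bulk", .data$feature_type == "bacteria")
  total_bases <- gt$design$reads_per_sample[["bulk"]] * 2 *
    gt$design$read_length
  host_depth <- bulk |>
    mutate(depth = .data$rel_abundance * total_bases / .data$length) |>
    select("sample_id", species_id = "feature_id", "depth")
  grid <- inner_join(ann, host_depth, by = "species_id",
                     relationship = "many-to-many")
  expected_breadth <- 1 - exp(-grid$depth)
  covered <- if (noise) {
    with_seed(derive_seed(seed, "orf-coverage"),
              rbinom(nrow(grid), size = as.integer(orf_length),
                     prob = expected_breadth))
  } else {
    round(expected_breadth * orf_length)
  }
  list(
    coverage = tibble(
      feature_id = grid$orf_id,
      sample_id = grid$sample_id,
      assay = "bulk",
      length = orf_length,
      covered_bases = as.numeric(covered),
      breadth = covered / orf_length,
      mean_depth = grid$depth
    ),
    annotations = ann
  )
}

#' Emit annotated contig inputs for the viral-discovery stage
#'
#' Produces one annotated contig per species/phage of the ground truth, with
#' gene annotations (structural proteins, lysogeny markers, metabolic genes)
#' laid out along the contig, phage-predictor flags, and CheckV-style
#' completeness/contamination. Optionally writes the FASTA, annotation TSV,
#' metadata TSV and ground-truth JSON to `dir`.
#'
#' @param gt a [build_community()] result.
#' @param dir optional output directory; created if missing.
#' @param sequences which contigs get simulated nucleotide sequences:
#'   `"viral"` (default), `"all"`, or `"none"`.
#' @param seed integer seed for sequence simulation.
#' @return A list with tibbles `contigs` and `genes` (and `paths` when `dir`
#'   is given).
#' @export
emit_catalog_inputs <- function(gt, dir = NULL,
                                sequences = c("viral", "all", "none"),
                                seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  sequences <- match.arg(sequences)
  p <- gt$phages
  b <- gt$bacteria

  phage_genes <- with_seed(derive_seed(seed, "phage-genes"), purrr::pmap_dfr(
    list(p$phage_id, p$structural_genes, p$lysogeny_markers, p$n_amg,
         p$genome_length),
    function(id, struct, lys, namg, len) {
      labels <- c(struct, lys,
                  if (namg > 0) sample(c("GH43", "K00925", "K01034"), namg))
      categories <- c(rep("structural", length(struct)),
                      rep("lysogeny_marker", length(lys)),
                      rep("metabolic", namg))
      n_other <- max(0, 8 - length(labels))
      labels <- c(labels, rep("none", n_other))
      categories <- c(categories, rep("other", n_other))
      k <- length(labels)
      width <- floor(len / k)
      tibble(
        contig_id = id,
        gene_id = sprintf("%s_g%02d", id, seq_len(k)),
        start = (seq_len(k) - 1) * width + 1,
        end = pmin((seq_len(k) - 1) * width + 900, len),
        strand = sample(c("+", "-"), k, replace = TRUE),
        category = categories,
        label = labels
      )
    }
  ))

  bact_genes <- purrr::map2_dfr(b$species_id, b$gene_complement,
    function(id, genes) {
      k <- length(genes)
      tibble(
        contig_id = id,
        gene_id = sprintf("%s_g%02d", id, seq_len(k)),
        start = (seq_len(k) - 1) * 1500 + 1,
        end = (seq_len(k) - 1) * 1500 + 1200,
        strand = "+",
        category = "metabolic",
        label = genes
      )
    })

  contigs <- bind_rows(
    tibble(
      contig_id = b$species_id,
      length = b$genome_length,
      source = "bin",
      kind = "bacterial",
      completeness_pct = 100,
      contamination_pct = 0,
      virsorter_like = FALSE,
      vibrant_like = FALSE,
      host_homology_evidence = FALSE,
      host_id = NA_character_
    ),
    tibble(
      contig_id = p$phage_id,
      length = p$genome_length,
      source = if_else(p$lifestyle_true == "temperate", "bin",
                       "vlp"),
      kind = "viral",
      completeness_pct = p$completeness_pct,
      contamination_pct = p$contamination_pct,
      virsorter_like = p$virsorter_like,
      vibrant_like = p$vibrant_like,
      host_homology_evidence = p$host_homology_evidence,
      host_id = p$host_id
    )
  )

  genes <- bind_rows(phage_genes, bact_genes)

  want_seq <- switch(sequences,
                     none = rep(FALSE, nrow(contigs)),
                     viral = contigs$kind == "viral",
                     all = rep(TRUE, nrow(contigs)))
  contigs$sequence <- NA_character_
  if (any(want_seq)) {
    contigs$sequence[want_seq] <- with_seed(derive_seed(seed, "sequences"), {
      vapply(contigs$length[want_seq], random_dna, character(1))
    })
  }

  out <- list(contigs = contigs, genes = genes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      annotations = file.path(dir, "annotations.tsv"),
      contigs = file.path(dir, "contigs.tsv"),
      fasta = file.path(dir, "contigs.fasta"),
      ground_truth = file.path(dir, "ground_truth.json")
    )
    write_annotations(genes, paths$annotations)
    readr::write_tsv(select(contigs, -"sequence"), paths$contigs)
    write_fasta(setNames(contigs$sequence[want_seq],
                         contigs$contig_id[want_seq]), paths$fasta)
    jsonlite::write_json(ground_truth_to_list(gt), paths$ground_truth,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ground_truth_to_list <- function(gt) {
  list(
    bacteria = gt$bacteria,
    phages = mutate(gt$phages,
                    structural_genes = vapply(.data$structural_genes,
                                              paste, character(1),
                                              collapse = ","),
                    lysogeny_markers = vapply(.data$lysogeny_markers,
                                              paste, character(1),
                                              collapse = ",")),
    design = gt$design,
    true_da_features = gt$true_da_features
  )
}

#' Simulate a complete paired bulk/VLP experiment
#'
#' Convenience wrapper chaining [build_community()],
#' [simulate_relative_abundances()], [simulate_coverage()] and
#' [simulate_gene_coverage()].
#'
#' @inheritParams build_community
#' @param genes also simulate bacterial gene (ORF) coverage?
#' @return A list of class `virome_sim` with elements `ground_truth`,
#'   `abundances`, `coverage`, `metadata`, and optionally `orfs`.
#' @export
simulate_experiment <- function(config = community_config(), seed = 1,
                                genes = FALSE) {
  gt <- build_community(config, seed)
  ab <- simulate_relative_abundances(gt, seed)
  cov <- simulate_coverage(ab, gt$design, seed, noise = config$noise)
  metadata <- ab |>
    distinct(.data$sample_id, .data$mouse_id, .data$group, .data$assay)
  out <- list(ground_truth = gt, abundances = ab, coverage = cov,
              metadata = metadata)
  if (genes) {
    out$orfs <- simulate_gene_coverage(gt, ab, seed, noise = config$noise)
  }
  structure(out, class = "virome_sim")
}
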