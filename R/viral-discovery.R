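#' Filter contigs on completeness and contamination
#'
#' Keeps putative viral genomes with completeness at least
#' `min_completeness` percent and contamination strictly below
#' `max_contamination` percent (CheckV-style estimates supplied as input
#' columns). Input order is preserved.
#'
#' @param contigs tibble with `contig_id`, `completeness_pct`,
#'   `contamination_pct`.
#' @param min_completeness minimum completeness, percent (kept when `>=`).
#' @param max_contamination maximum contamination, percent (kept when `<`).
#' @return The retained rows of `contigs`.
#' @export
filter_completeness <- function(contigs, min_completeness = 50,
                                max_contamination = 10) {
  assert_columns(contigs, c("contig_id", "completeness_pct",
                            "contamination_pct"))
  bad <- is.na(contigs$completeness_pct) | is.na(contigs$contamination_pct)
  if (any(bad)) {
    abort(sprintf("missing completeness/contamination for contig(s): %s",
                  paste(contigs$contig_id[bad], collapse = ", ")))
  }
  contigs[contigs$completeness_pct >= min_completeness &
            contigs$contamination_pct < max_contamination, , drop = FALSE]
}

#' Dereplicate contigs into species-level representatives
#'
#' Greedy clustering in descending length order (ties broken by
#' lexicographic `contig_id`): a contig joins an existing representative if
#' its best ungapped containment alignment covers at least
#' `min_short_coverage` of the shorter sequence at identity at least
#' `min_identity`. Candidate alignments are found by exact 21-mer
#' seed-and-extend on a shared diagonal; identity is matches over the
#' aligned span of the shorter sequence. Contigs without sequence cannot be
#' compared and become their own representatives.
#'
#' @param contigs tibble with `contig_id`, `length`, and a character
#'   `sequence` column (may be `NA`).
#' @param min_identity minimum fractional identity (default 0.99).
#' @param min_short_coverage minimum fraction of the shorter sequence that
#'   must be aligned (default 1, i.e. full containment).
#' @param k seed k-mer length.
#' @return A list with `representatives` (rows of `contigs`, longest member
#'   of each cluster, deterministic order) and `clusters` (tibble
#'   `contig_id`, `representative_id`).
#' @export
dereplicate <- function(contigs, min_identity = 0.99,
                        min_short_coverage = 1.0, k = 21) {
  assert_columns(contigs, c("contig_id", "length"))
  if (nrow(contigs) == 0) {
    return(list(representatives = contigs,
                clusters = tibble(contig_id = character(0),
                                  representative_id = character(0))))
  }
  if (!"sequence" %in% names(contigs)) contigs$sequence <- NA_character_
  ord <- order(-contigs$length, contigs$contig_id)
  contigs <- contigs[ord, , drop = FALSE]

  rep_ids <- character(0)
  rep_seqs <- list()      # representative sequence (character)
  rep_kmers <- list()     # representative k-mer vector
  assignment <- character(nrow(contigs))

  for (i in seq_len(nrow(contigs))) {
    id <- contigs$contig_id[i]
    s <- contigs$sequence[i]
    joined <- NA_character_
    if (!is.na(s) && nchar(s) >= k) {   # sequence-less contigs stand alone
      for (j in seq_along(rep_ids)) {
        if (is.null(rep_seqs[[j]])) next
        hit <- containment_match(s, rep_seqs[[j]], rep_kmers[[j]],
                                 min_identity, min_short_coverage, k)
        if (hit) {
          joined <- rep_ids[j]
          break
        }
      }
    }
    if (is.na(joined)) {
      rep_ids <- c(rep_ids, id)
      if (!is.na(s) && nchar(s) >= k) {
        rep_seqs[[length(rep_ids)]] <- s
        rep_kmers[[length(rep_ids)]] <- seq_kmers(s, k)
      } else {
        rep_seqs[length(rep_ids)] <- list(NULL)
        rep_kmers[length(rep_ids)] <- list(NULL)
      }
      assignment[i] <- id
    } else {
      assignment[i] <- joined
    }
  }

  clusters <- tibble(contig_id = contigs$contig_id,
                     representative_id = assignment)
  representatives <- contigs[contigs$contig_id %in% rep_ids, , drop = FALSE]
  list(representatives = representatives, clusters = clusters)
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# Best ungapped containment of `query` within `target`: seed diagonals from
# exact k-mer matches, then count matches over the aligned span.
containment_match <- function(query, target, target_kmers, min_identity,
                              min_short_coverage, k) {
  qlen <- nchar(query)
  tlen <- nchar(target)
  if (qlen > tlen) return(FALSE)
  starts <- unique(c(seq(1, qlen - k + 1, by = 50), qlen - k + 1))
  qk <- substring(query, starts, starts + k - 1)
  tpos <- match(qk, target_kmers)
  found <- !is.na(tpos)
  if (!any(found)) return(FALSE)
  diagonals <- tpos[found] - starts[found]     # target offset of query pos 1 - 1
  tab <- sort(table(diagonals), decreasing = TRUE)
  cand <- as.integer(names(tab))[seq_len(min(length(tab), 20))]
  qraw <- charToRaw(query)
  traw <- charToRaw(target)
  for (d in cand) {
    q_from <- max(1, 1 - d)
    q_to <- min(qlen, tlen - d)
    span <- q_to - q_from + 1
    if (span < min_short_coverage * qlen) next
    matches <- sum(qraw[q_from:q_to] == traw[(q_from + d):(q_to + d)])
    if (matches / span >= min_identity &&
        span / qlen >= min_short_coverage) {
      return(TRUE)
    }
  }
  FALSE
}

#' Validate putative viral contigs
#'
#' A contig passes when (i) it was flagged by at least one phage predictor
#' (VirSorter-like or VIBRANT-like input flags), (ii) it encodes at least
#' one phage structural protein (terminase, capsid, tail,
#' N-acetylmuramoyl-L-alanine amidase, baseplate, prohead, coat or virion),
#' and (iii) it is not a single-structural-gene contig with more than 100
#' ORFs (a pattern typical of mis-flagged bacterial fragments). The ORF
#' count is the number of annotated genes on the contig.
#'
#' @param contigs tibble with `contig_id`, `virsorter_like`, `vibrant_like`.
#' @param genes annotation tibble with `contig_id`, `category`.
#' @return A tibble `contig_id`, `verdict` (`"pass"`/`"fail"`), `reason`
#'   (`NA`, `"no_predictor"`, `"no_structural"`,
#'   `"single_structural_large"`), `n_structural`, `n_orfs`; one row per
#'   input contig, input order.
#' @export
validate_viral <- function(contigs, genes) {
  assert_columns(contigs, c("contig_id", "virsorter_like", "vibrant_like"))
  assert_columns(genes, c("contig_id", "category"))
  counts <- genes |>
    group_by(.data$contig_id) |>
    summarise(n_orfs = n(),
              n_structural = sum(.data$category == "structural"),
              .groups = "drop")
  out <- contigs |>
    select("contig_id", "virsorter_like", "vibrant_like") |>
    left_join(counts, by = "contig_id") |>
    mutate(n_orfs = dplyr::coalesce(.data$n_orfs, 0L),
           n_structural = dplyr::coalesce(.data$n_structural, 0L))
  reason <- rep(NA_character_, nrow(out))
  reason[out$n_structural == 1 & out$n_orfs > 100] <- "single_structural_large"
  reason[out$n_structural < 1] <- "no_structural"
  reason[!out$virsorter_like & !out$vibrant_like] <- "no_predictor"
  out$verdict <- if_else(is.na(reason), "pass", "fail")
  out$reason <- reason
  select(out, "contig_id", "verdict", "reason", "n_structural", "n_orfs")
}

#' Classify validated viral contigs as temperate or virulent
#'
#' A contig is called temperate when it carries at least one
#' lysogeny-associated gene (integrase, transposase, recombinase or Cro/CI
#' domain) or shows homology with a bacterial genome flanked by bacterial
#' regions (the `host_homology_evidence` input flag); otherwise it is called
#' virulent.
#'
#' @param contigs tibble with `contig_id`, `host_homology_evidence`.
#' @param genes annotation tibble with `contig_id`, `category`.
#' @return A tibble `contig_id`, `lifestyle`, input order.
#' @export
classify_lifestyle <- function(contigs, genes) {
  assert_columns(contigs, c("contig_id", "host_homology_evidence"))
  assert_columns(genes, c("contig_id", "category"))
  has_marker <- genes |>
    filter(.data$category == "lysogeny_marker") |>
    distinct(.data$contig_id) |>
    pull("contig_id")
  tibble(
    contig_id = contigs$contig_id,
    lifestyle = if_else(contigs$contig_id %in% has_marker |
                          contigs$host_homology_evidence,
                        "temperate", "virulent")
  )
}

#' Build the validated viral catalog
#'
#' Runs the full validation cascade: completeness/contamination filter,
#' dereplication into species-level representative genomes (SRGs),
#' predictor/structural validation, and lifestyle classification.
#'
#' @param contigs annotated contig tibble (`contig_id`, `length`,
#'   `completeness_pct`, `contamination_pct`, `virsorter_like`,
#'   `vibrant_like`, `host_homology_evidence`, optional `host_id`,
#'   `family`, `sequence`).
#' @param genes gene annotation tibble.
#' @inheritParams filter_completeness
#' @inheritParams dereplicate
#' @return A tibble of class `viral_catalog` with columns `srg_id`,
#'   `length`, `lifestyle`, `host_id`, `amg_count`, `n_members`, `members`
#'   (comma-separated contig ids) and `family` (NA when not supplied).
#'   Attributes: `clusters` (the dereplication map) and `filter_counts`
#'   (discards at each cascade step).
#' @export
build_viral_catalog <- function(contigs, genes, min_completeness = 50,
                                max_contamination = 10, min_identity = 0.99,
                                min_short_coverage = 1.0) {
  empty <- tibble(srg_id = character(0), length = numeric(0),
                  lifestyle = character(0), host_id = character(0),
                  amg_count = integer(0), n_members = integer(0),
                  members = character(0), family = character(0))
  if (nrow(contigs) == 0) {
    return(structure(empty, class = c("viral_catalog", class(empty)),
                     filter_counts = c(completeness = 0L, validation = 0L)))
  }
  kept <- filter_completeness(contigs, min_completeness, max_contamination)
  n_completeness <- nrow(contigs) - nrow(kept)

  derep <- dereplicate(kept, min_identity, min_short_coverage)
  reps <- derep$representatives

  verdicts <- validate_viral(reps, genes)
  pass_ids <- verdicts$contig_id[verdicts$verdict == "pass"]
  n_validation <- nrow(reps) - length(pass_ids)
  reps <- reps[reps$contig_id %in% pass_ids, , drop = FALSE]

  lifestyles <- classify_lifestyle(reps, genes)

  amg <- genes |>
    filter(.data$category == "metabolic") |>
    group_by(.data$contig_id) |>
    summarise(amg_count = n(), .groups = "drop")

  members <- derep$clusters |>
    group_by(.data$representative_id) |>
    summarise(n_members = n(),
              members = paste(sort(.data$contig_id), collapse = ","),
              .groups = "drop")

  catalog <- reps |>
    select(srg_id = "contig_id", "length",
           dplyr::any_of(c("host_id", "family"))) |>
    left_join(lifestyles, by = c(srg_id = "contig_id")) |>
    left_join(amg, by = c(srg_id = "contig_id")) |>
    left_join(members, by = c(srg_id = "representative_id")) |>
    mutate(amg_count = dplyr::coalesce(.data$amg_count, 0L))
  if (!"host_id" %in% names(catalog)) catalog$host_id <- NA_character_
  if (!"family" %in% names(catalog)) catalog$family <- NA_character_
  catalog$host_id[catalog$lifestyle == "virulent"] <- NA_character_
  catalog <- select(catalog, "srg_id", "length", "lifestyle", "host_id",
                    "amg_count", "n_members", "members", "family")
  structure(catalog, class = c("viral_catalog", class(empty)),
            clusters = derep$clusters,
            filter_counts = c(completeness = n_completeness,
                              validation = n_validation))
}
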