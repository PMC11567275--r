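#' Default subsampling grid for depth-saturation analysis
#'
#' Bulk metagenomes are subsampled at 1, 5, 10, 15, 20 and 25 million
#' paired-end reads and VLP metagenomes at 1, 5, 10 and 15 million, in
#' triplicate.
#'
#' @param bulk_depths,vlp_depths strictly increasing PE read counts.
#' @param replicates subsampling replicates per depth.
#' @return A list of class `depth_grid`.
#' @export
depth_grid <- function(bulk_depths = c(1, 5, 10, 15, 20, 25) * 1e6,
                       vlp_depths = c(1, 5, 10, 15) * 1e6,
                       replicates = 3) {
  if (any(diff(bulk_depths) <= 0) || any(diff(vlp_depths) <= 0)) {
    abort("depths must be strictly increasing")
  }
  if (replicates < 1) abort("replicates must be >= 1")
  structure(list(bulk_depths = bulk_depths, vlp_depths = vlp_depths,
                 replicates = replicates), class = "depth_grid")
}

#' Thin coverage records to a fraction of their sequencing depth
#'
#' Emulates read subsampling at the coverage level: mean depth scales by
#' `fraction` and breadth follows the Lander-Waterman expectation
#' `1 - exp(-lambda')` at the thinned depth, with binomial noise on covered
#' positions, never exceeding the original breadth. `fraction = 1` is the
#' identity.
#'
#' @param records coverage tibble.
#' @param fraction thinning fraction in (0, 1].
#' @param seed integer seed.
#' @param noise draw binomial noise on covered positions?
#' @return The thinned coverage tibble (identity fields untouched).
#' @export
thin_coverage <- function(records, fraction, seed = 1, noise = TRUE) {
  if (length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]")
  }
  if (fraction == 1) return(records)
  lambda <- records$mean_depth * fraction
  expected <- pmin(1 - exp(-lambda), records$breadth)
  covered <- if (noise) {
    with_seed(derive_seed(seed, paste0("thin-", fraction)),
              rbinom(nrow(records), size = as.integer(records$length),
                     prob = expected))
  } else {
    round(expected * records$length)
  }
  covered <- pmin(covered, records$covered_bases)
  mutate(records,
         mean_depth = lambda,
         covered_bases = as.numeric(covered),
         breadth = covered / .data$length)
}

#' Rarefaction curve of SRG recovery versus sequencing depth
#'
#' Thins a sample's coverage records to each grid depth, applies the
#' presence call, and counts recovered SRGs, in replicate.
#'
#' @param records coverage tibble for one sample/assay.
#' @param kind `"viral"` or `"bacterial"` (see [call_presence()]).
#' @param depths PE read depths to evaluate.
#' @param native_depth the sample's native PE read depth; requested depths
#'   may not exceed it.
#' @param replicates thinning replicates per depth.
#' @param seed integer seed.
#' @param noise draw binomial noise when thinning?
#' @return A tibble `depth`, `replicate`, `n_detected`.
#' @export
rarefaction_curve <- function(records, kind, depths, native_depth,
                              replicates = 3, seed = 1, noise = TRUE) {
  if (any(depths > native_depth)) {
    abort("requested depth exceeds the native sequencing depth")
  }
  if (nrow(records) == 0) {
    return(tidyr::expand_grid(depth = depths,
                              replicate = seq_len(replicates)) |>
             mutate(n_detected = 0L))
  }
  purrr::map_dfr(depths, function(d) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      thinned <- thin_coverage(records, d / native_depth,
                               seed = derive_seed(seed, paste(d, r)),
                               noise = noise)
      called <- call_presence(thinned, kind)
      tibble(depth = d, replicate = r,
             n_detected = sum(called$present))
    })
  })
}

#' Detect the saturation plateau of a rarefaction curve
#'
#' Returns the smallest grid depth after which every consecutive increase of
#' the (replicate-mean) curve is below `epsilon` times the final count. When
#' no such depth exists the largest depth is returned, flagged unsaturated.
#'
#' @param curve output of [rarefaction_curve()] (replicates are averaged) or
#'   a tibble with `depth` and `n_detected`.
#' @param epsilon plateau tolerance as a fraction of the final count.
#' @return A list with `depth`, `saturated` (logical) and `epsilon`.
#' @export
detect_plateau <- function(curve, epsilon = 0.02) {
  means <- curve |>
    group_by(.data$depth) |>
    summarise(n = mean(.data$n_detected), .groups = "drop") |>
    arrange(.data$depth)
  if (nrow(means) < 2) abort("need at least 2 grid depths")
  increases <- diff(means$n)
  tol <- epsilon * means$n[nrow(means)]
  # plateau at depth i requires every increase after i to be < tol
  ok_after <- rev(cumall_strict(rev(increases) < tol))
  idx <- which(ok_after)
  if (length(idx) == 0) {
    list(depth = means$depth[nrow(means)], saturated = FALSE,
         epsilon = epsilon)
  } else {
    list(depth = means$depth[min(idx)], saturated = TRUE, epsilon = epsilon)
  }
}

# cumulative "all so far TRUE" without dropping to O(n^2)
cumall_strict <- function(x) cumsum(!x) == 0

#' Fraction of VLP-derived SRGs captured in the bulk metagenome
#'
#' For each breadth threshold and bulk depth, the percentage of the VLP
#' viral catalog whose bulk breadth (after thinning to that depth) reaches
#' the threshold.
#'
#' @param bulk_records coverage tibble of the bulk sample over the viral
#'   catalog.
#' @param vlp_ids character vector of viral SRGs detected in the VLP
#'   metagenome (the reference catalog).
#' @param depths bulk PE read depths to evaluate.
#' @param native_depth native bulk PE read depth.
#' @param breadth_thresholds length-coverage thresholds (default 10%, 25%,
#'   50%, 70%, 90%).
#' @param seed integer seed.
#' @param noise draw binomial noise when thinning?
#' @return A tibble of class `capture_grid`: `breadth_threshold`, `depth`,
#'   `n_captured`, `capture_pct`.
#' @export
capture_fraction <- function(bulk_records, vlp_ids, depths, native_depth,
                             breadth_thresholds = c(0.10, 0.25, 0.50,
                                                    0.70, 0.90),
                             seed = 1, noise = TRUE) {
  if (length(vlp_ids) == 0) abort("the VLP catalog is empty")
  if (any(depths > native_depth)) {
    abort("requested depth exceeds the native sequencing depth")
  }
  target <- filter(bulk_records, .data$feature_id %in% vlp_ids)
  grid <- purrr::map_dfr(depths, function(d) {
    thinned <- thin_coverage(target, d / native_depth,
                             seed = derive_seed(seed, paste("capture", d)),
                             noise = noise)
    purrr::map_dfr(breadth_thresholds, function(t) {
      n_cap <- length(unique(
        thinned$feature_id[thinned$breadth >= t]))
      tibble(breadth_threshold = t, depth = d, n_captured = n_cap,
             capture_pct = 100 * n_cap / length(vlp_ids))
    })
  })
  structure(grid, class = c("capture_grid", class(grid)))
}
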