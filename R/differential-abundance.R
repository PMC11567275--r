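#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median ratio of a
#' sample's counts to the per-feature geometric means (features with any
#' zero count are excluded from the reference), rescaled to geometric mean
#' one. When no feature is nonzero in every sample, the reference falls
#' back to geometric means over positive counts only and the result is
#' flagged.
#'
#' @param counts features x samples numeric matrix (or a
#'   `virome_feature_table`).
#' @return Named numeric vector of size factors; attribute `fallback` is
#'   `TRUE` when the positive-count fallback was used.
#' @export
size_factors_median_ratio <- function(counts) {
  m <- count_matrix(counts)
  all_pos <- rowSums(m == 0) == 0
  fallback <- !any(all_pos)
  if (fallback) {
    log_gm <- apply(m, 1, function(x) mean(log(x[x > 0])))
    ratios <- log(m) - log_gm
    factors <- apply(ratios, 2, function(r) exp(median(r[is.finite(r)])))
  } else {
    ref <- m[all_pos, , drop = FALSE]
    log_gm <- rowMeans(log(ref))
    factors <- apply(log(ref) - log_gm, 2, function(r) exp(median(r)))
  }
  factors <- factors / exp(mean(log(factors)))
  structure(factors, fallback = fallback)
}

count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
    rownames(m) <- if ("feature_id" %in% names(counts)) counts$feature_id
                   else paste0("f", seq_len(nrow(counts)))
    m
  } else {
    m <- as.matrix(counts)
    if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
    m
  }
}

split_groups <- function(labels, reference = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) abort("differential abundance needs exactly 2 groups")
  if (!is.null(reference)) {
    if (!reference %in% lev) abort("reference is not one of the groups")
    lev <- c(reference, setdiff(lev, reference))
  }
  if (min(table(labels)) < 2) abort("every group needs at least 2 samples")
  list(reference = lev[1], other = lev[2],
       ref_idx = which(labels == lev[1]),
       other_idx = which(labels == lev[2]))
}

#' Negative-binomial Wald differential abundance
#'
#' DESeq-family engine: counts are normalised by median-of-ratios size
#' factors, a per-feature dispersion is estimated by method of moments
#' (floored at 1e-8), the log2 fold change is the ratio of group means with
#' a pseudo-mean of 0.5, and a Wald z test against the delta-method
#' standard error yields two-sided normal p-values. Features with zero
#' counts in all samples are excluded and reported.
#'
#' @param counts features x samples counts.
#' @param labels two-group factor over samples.
#' @param reference reference group (log2FC is other vs reference).
#' @return A tibble `feature_id`, `log2fc`, `se`, `p_value`; attribute
#'   `excluded` lists all-zero features.
#' @export
nb_wald <- function(counts, labels, reference = NULL) {
  m <- count_matrix(counts)
  grp <- split_groups(labels, reference)
  keep <- rowSums(m) > 0
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  sf <- size_factors_median_ratio(m)
  norm <- sweep(m, 2, sf, `/`)

  ref <- norm[, grp$ref_idx, drop = FALSE]
  oth <- norm[, grp$other_idx, drop = FALSE]
  mu_ref <- rowMeans(ref)
  mu_oth <- rowMeans(oth)

  # method-of-moments NB dispersion pooled over groups
  pooled_var <- (apply(ref, 1, var) * (ncol(ref) - 1) +
                   apply(oth, 1, var) * (ncol(oth) - 1)) /
    (ncol(ref) + ncol(oth) - 2)
  mu_bar <- (mu_ref + mu_oth) / 2
  dispersion <- pmax((pooled_var - mu_bar) / mu_bar^2, 1e-8)

  log2fc <- log2((mu_oth + 0.5) / (mu_ref + 0.5))
  var_log_ref <- (1 / pmax(mu_ref, 0.5) + dispersion) / ncol(ref)
  var_log_oth <- (1 / pmax(mu_oth, 0.5) + dispersion) / ncol(oth)
  se <- sqrt(var_log_ref + var_log_oth) / log(2)
  z <- log2fc / se
  tibble(feature_id = rownames(m), log2fc = unname(log2fc),
         se = unname(se), p_value = unname(2 * pnorm(-abs(z)))) |>
    structure(excluded = excluded, reference = grp$reference)
}

#' Log-transformed relative-abundance linear model
#'
#' MaAsLin-family engine: counts are total-sum scaled per sample, shifted
#' by half the smallest positive relative abundance, log2-transformed, and
#' each feature is tested with an equal-variance two-group linear model
#' (two-sided t). Features with identical values in every sample get p = 1.
#'
#' @inheritParams nb_wald
#' @return A tibble `feature_id`, `estimate`, `p_value`.
#' @export
lm_logtss <- function(counts, labels, reference = NULL) {
  m <- count_matrix(counts)
  grp <- split_groups(labels, reference)
  rel <- sweep(m, 2, colSums(m), `/`)
  pseudo <- min(rel[rel > 0]) / 2
  y <- log2(rel + pseudo)

  ref <- y[, grp$ref_idx, drop = FALSE]
  oth <- y[, grp$other_idx, drop = FALSE]
  n1 <- ncol(ref)
  n2 <- ncol(oth)
  est <- rowMeans(oth) - rowMeans(ref)
  pooled_var <- (apply(ref, 1, var) * (n1 - 1) +
                   apply(oth, 1, var) * (n2 - 1)) / (n1 + n2 - 2)
  se <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  p <- ifelse(se == 0,
              ifelse(est == 0, 1, 0),
              2 * pt(-abs(est / se), df = n1 + n2 - 2))
  # a feature constant across all samples carries no signal
  p[apply(y, 1, function(v) length(unique(v)) == 1)] <- 1
  tibble(feature_id = rownames(m), estimate = unname(est),
         p_value = unname(p))
}

#' Cumulative-sum-scaling moderated test
#'
#' metagenomeSeq-family engine: each sample is scaled by the cumulative sum
#' of its counts up to the median (50th percentile) of its positive counts,
#' re-referenced to the median scaling factor, log2(x + 1)-transformed, and
#' each feature tested with a moderated two-group t statistic whose
#' variance is shrunk halfway toward the across-feature mean variance
#' (prior weight 0.5, pooled degrees of freedom).
#'
#' @inheritParams nb_wald
#' @return A tibble `feature_id`, `estimate`, `p_value`; attribute
#'   `css_factors` carries the per-sample scaling factors.
#' @export
css_moderated <- function(counts, labels, reference = NULL) {
  m <- count_matrix(counts)
  grp <- split_groups(labels, reference)
  factors <- apply(m, 2, function(x) {
    pos <- x[x > 0]
    if (length(pos) < 2) return(sum(x))   # flagged degenerate sample
    sum(pos[pos <= quantile(pos, 0.5)])
  })
  ref_factor <- median(factors)
  scaled <- sweep(m, 2, factors, `/`) * ref_factor
  y <- log2(scaled + 1)

  ref <- y[, grp$ref_idx, drop = FALSE]
  oth <- y[, grp$other_idx, drop = FALSE]
  n1 <- ncol(ref)
  n2 <- ncol(oth)
  est <- rowMeans(oth) - rowMeans(ref)
  s2 <- (apply(ref, 1, var) * (n1 - 1) + apply(oth, 1, var) * (n2 - 1)) /
    (n1 + n2 - 2)
  s2_shrunk <- 0.5 * s2 + 0.5 * mean(s2)
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  df <- 2 * (n1 + n2 - 2)  # residual + equally-weighted prior df
  p <- ifelse(se == 0,
              ifelse(est == 0, 1, 0),
              2 * pt(-abs(est / se), df = df))
  tibble(feature_id = rownames(m), estimate = unname(est),
         p_value = unname(p)) |>
    structure(css_factors = factors)
}

#' Consensus differential abundance
#'
#' A feature is called differentially abundant when all three engines are
#' significant after per-engine Benjamini-Hochberg correction
#' (`q < alpha`) and the NB-Wald log2 fold change exceeds `lfc_threshold`
#' in magnitude.
#'
#' @param nb,lm,css results of [nb_wald()], [lm_logtss()],
#'   [css_moderated()] on the same features.
#' @param lfc_threshold |log2FC| cutoff (default 2).
#' @param alpha FDR-adjusted significance level (default 0.05).
#' @return A tibble of class `virome_da`: `feature_id`, `log2fc`, `p_nb`,
#'   `p_lm`, `p_zig`, `q_nb`, `q_lm`, `q_zig`, `consensus`.
#' @export
consensus <- function(nb, lm, css, lfc_threshold = 2, alpha = 0.05) {
  if (!setequal(nb$feature_id, lm$feature_id) ||
      !setequal(nb$feature_id, css$feature_id)) {
    abort("the three engines must be run on identical feature sets")
  }
  out <- nb |>
    select("feature_id", "log2fc", p_nb = "p_value") |>
    left_join(select(lm, "feature_id", p_lm = "p_value"),
              by = "feature_id") |>
    left_join(select(css, "feature_id", p_zig = "p_value"),
              by = "feature_id") |>
    mutate(q_nb = p.adjust(.data$p_nb, "BH"),
           q_lm = p.adjust(.data$p_lm, "BH"),
           q_zig = p.adjust(.data$p_zig, "BH"),
           consensus = .data$q_nb < alpha & .data$q_lm < alpha &
             .data$q_zig < alpha & abs(.data$log2fc) > lfc_threshold)
  structure(out, class = c("virome_da", class(out)),
            lfc_threshold = lfc_threshold, alpha = alpha,
            reference = attr(nb, "reference"))
}

#' Run the full three-engine consensus differential abundance analysis
#'
#' @param table a `virome_feature_table` (integer counts).
#' @param labels two-group factor over the table's samples (column order).
#' @param reference reference group; reported log2FC is other vs reference.
#' @inheritParams consensus
#' @return A `virome_da` tibble (see [consensus()]).
#' @export
da_consensus <- function(table, labels, reference = NULL,
                         lfc_threshold = 2, alpha = 0.05) {
  m <- count_matrix(table)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  nb <- nb_wald(m, labels, reference)
  lmres <- lm_logtss(m, labels, reference)
  cssres <- css_moderated(m, labels, reference)
  consensus(nb, lmres, cssres, lfc_threshold, alpha)
}
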