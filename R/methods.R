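#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.virome_permanova <- function(x, ...) {
  cat(sprintf("%s: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$R2, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.virome_permanova <- function(x, ...) {
  tibble(term = "group", statistic = x$statistic, R2 = x$R2,
         p.value = x$p_value, n.perm = x$n_perm, method = x$method)
}

#' @export
glance.virome_permanova <- function(x, ...) tidy(x)

#' @export
print.virome_procrustes <- function(x, ...) {
  cat(sprintf("%s: m2 = %.4f, r = %.3f, p = %.4g (%d permutations)\n",
              x$method, x$m2, x$r, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.virome_procrustes <- function(x, ...) {
  tibble(statistic = x$m2, r = x$r, p.value = x$p_value,
         n.perm = x$n_perm, method = x$method)
}

#' @export
glance.virome_procrustes <- function(x, ...) tidy(x)

#' @export
print.virome_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  cat(sprintf("  gates: Shapiro-Wilk p = %.3g, Levene p = %.3g\n",
              x$normality_p, x$levene_p))
  invisible(x)
}

#' @export
tidy.virome_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p_value,
         shapiro.p = x$normality_p, levene.p = x$levene_p)
}

#' @export
tidy.virome_pcoa <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         prop_explained = x$prop_explained)
}

#' @export
glance.virome_pcoa <- function(x, ...) {
  tibble(n_axes = length(x$eigenvalues),
         n_negative_dropped = x$n_negative_dropped,
         prop_first_two = sum(x$prop_explained[seq_len(
           min(2, length(x$prop_explained)))]))
}

#' @export
glance.virome_da <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_consensus = sum(x$consensus),
         lfc_threshold = attr(x, "lfc_threshold"),
         alpha = attr(x, "alpha"))
}

#' Ordination scatter plot
#'
#' @param object a `virome_pcoa`.
#' @param colour optional vector (e.g. group labels) to colour samples by.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.virome_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) df$Axis2 <- 0
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::geom_point(
      if (is.null(colour)) NULL
      else ggplot2::aes(colour = .data$colour), size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_explained[1]),
      y = sprintf("PCo2 (%.1f%%)",
                  100 * ifelse(length(object$prop_explained) > 1,
                               object$prop_explained[2], 0)),
      colour = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Volcano plot of a consensus differential-abundance result
#'
#' @param object a `virome_da` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.virome_da <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$q_nb, 1e-300)),
                               colour = .data$consensus)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-attr(object, "lfc_threshold"),
                                       attr(object, "lfc_threshold")),
                        linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q (NB engine)",
                  colour = "consensus") +
    ggplot2::theme_minimal()
}

#' Rarefaction curve plot
#'
#' @param curve output of [rarefaction_curve()].
#' @return A ggplot of mean recovered SRGs vs depth with replicate points.
#' @export
plot_rarefaction <- function(curve) {
  means <- curve |>
    group_by(.data$depth) |>
    summarise(n = mean(.data$n_detected), .groups = "drop")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth / 1e6,
                                      y = .data$n_detected)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$n), linewidth = 0.8) +
    ggplot2::labs(x = "PE reads (millions)", y = "recovered SRGs") +
    ggplot2::theme_minimal()
}

#' Capture-grid tile plot
#'
#' @param grid a `capture_grid` from [capture_fraction()].
#' @return A ggplot tile plot of capture percentage by depth and breadth
#'   threshold.
#' @export
plot_capture_grid <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = factor(.data$depth / 1e6),
                               y = factor(.data$breadth_threshold),
                               fill = .data$capture_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$capture_pct)), size = 3) +
    ggplot2::labs(x = "bulk PE reads (millions)",
                  y = "breadth threshold", fill = "% captured") +
    ggplot2::theme_minimal()
}

#' Lifestyle totals plot
#'
#' @param totals output of [lifestyle_totals()].
#' @return A ggplot of per-sample total relative abundance by lifestyle.
#' @export
plot_lifestyle_totals <- function(totals) {
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$lifestyle,
                                       y = .data$total)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "total relative abundance") +
    ggplot2::theme_minimal()
}

#' @export
print.virome_report <- function(x, ...) {
  cat("Dual-source virome run report\n")
  cat(sprintf("  scenario: %s, seed %d\n", x$config$scenario, x$seed))
  cat(sprintf("  viral catalog: %d SRGs (%d temperate, %d virulent)\n",
              x$catalog$total, x$catalog$temperate, x$catalog$virulent))
  for (nm in names(x$stats$per_table)) {
    st <- x$stats$per_table[[nm]]
    cat(sprintf("  %s: PERMANOVA R2 = %.3f, p = %.4g\n", nm,
                st$permanova$R2, st$permanova$p))
  }
  cat(sprintf("  Procrustes viral~bacterial: r = %.3f, p = %.4g\n",
              x$stats$procrustes$r, x$stats$procrustes$p))
  for (nm in names(x$differential_abundance)) {
    cat(sprintf("  consensus DA (%s): %d feature(s)\n", nm,
                x$differential_abundance[[nm]]$n_consensus))
  }
  invisible(x)
}
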