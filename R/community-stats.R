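#' Per-sample alpha diversity
#'
#' Computes diversity indices from an integer feature table. `observed` is
#' the number of detected features; `chao1` is `S + F1^2 / (2 F2)` (or the
#' bias-corrected `S + F1 (F1 - 1) / 2` when no doubletons exist); `ace`
#' uses the standard abundance-based coverage estimator with rare threshold
#' 10; `shannon` is `-sum(p log p)` (natural log) and `simpson` is
#' `1 - sum(p^2)`.
#'
#' @param table a `virome_feature_table` of integer counts.
#' @param metric one of `"observed"`, `"chao1"`, `"ace"`, `"shannon"`,
#'   `"simpson"`.
#' @return A tibble `sample_id`, `metric`, `value`.
#' @export
alpha_diversity <- function(table, metric = c("observed", "chao1", "ace",
                                              "shannon", "simpson")) {
  metric <- match.arg(metric)
  samples <- setdiff(names(table), "feature_id")
  values <- vapply(samples, function(s) {
    x <- table[[s]]
    if (sum(x) == 0) {
      warn(sprintf("sample '%s' has no detected features; %s set to 0",
                   s, metric))
      return(0)
    }
    alpha_one(x[x > 0], metric)
  }, numeric(1))
  tibble(sample_id = samples, metric = metric, value = unname(values))
}

alpha_one <- function(x, metric) {
  switch(metric,
    observed = length(x),
    shannon = {
      p <- x / sum(x)
      -sum(p * log(p))
    },
    simpson = {
      p <- x / sum(x)
      1 - sum(p^2)
    },
    chao1 = chao1_index(x),
    ace = ace_index(x)
  )
}

chao1_index <- function(x) {
  s <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

ace_index <- function(x, rare_threshold = 10) {
  rare <- x[x <= rare_threshold]
  s_abund <- sum(x > rare_threshold)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  if (n_rare == 0) return(s_abund)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1_index(x))  # all rares are singletons
  fk <- tabulate(rare, nbins = rare_threshold)
  gamma2 <- max(s_rare / c_ace *
                  sum(seq_len(rare_threshold) *
                        (seq_len(rare_threshold) - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Bray-Curtis distance between samples
#'
#' `d(i, j) = sum |x - y| / sum (x + y)` over features. The distance between
#' two all-zero samples is defined as 0 and flagged.
#'
#' @param table a feature table (counts or relative abundances).
#' @return A [stats::dist] object labelled by sample id; attribute
#'   `zero_pairs` lists any all-zero sample pairs.
#' @export
bray_curtis <- function(table) {
  samples <- setdiff(names(table), "feature_id")
  m <- as.matrix(table[samples])
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  zero_pairs <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[, i] + m[, j])
      if (denom == 0) {
        d[i, j] <- d[j, i] <- 0
        zero_pairs <- c(zero_pairs, paste(samples[i], samples[j], sep = "/"))
      } else {
        d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
      }
    }
  }
  out <- as.dist(d)
  attr(out, "zero_pairs") <- zero_pairs
  out
}

#' Principal coordinates analysis
#'
#' Classical PCoA: Gower double-centering of `-d^2 / 2` followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are dropped
#' and their count reported.
#'
#' @param d a [stats::dist] or symmetric distance matrix with labels.
#' @return An object of class `virome_pcoa`: `coordinates` (tibble
#'   `sample_id`, `Axis1`, ...), `eigenvalues` (retained, decreasing),
#'   `prop_explained`, `n_negative_dropped`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  n <- nrow(m)
  a <- -0.5 * m^2
  centerer <- diag(n) - matrix(1 / n, n, n)
  b <- centerer %*% a %*% centerer
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  if (all(abs(eig$values) <= tol)) {
    coords <- tibble(sample_id = ids, Axis1 = rep(0, n))
    return(structure(list(coordinates = coords, eigenvalues = 0,
                          prop_explained = 1, n_negative_dropped = 0L),
                     class = "virome_pcoa"))
  }
  pos <- eig$values > tol
  values <- eig$values[pos]
  vectors <- eig$vectors[, pos, drop = FALSE]
  coords <- sweep(vectors, 2, sqrt(values), `*`)
  colnames(coords) <- paste0("Axis", seq_along(values))
  structure(
    list(
      coordinates = bind_cols(tibble(sample_id = ids), as_tibble(coords)),
      eigenvalues = values,
      prop_explained = values / sum(values),
      n_negative_dropped = sum(eig$values < -tol)
    ),
    class = "virome_pcoa"
  )
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: the pseudo-F statistic is
#' computed from total and within-group sums of squared distances and its
#' null distribution obtained by permuting group labels. With
#' `exhaustive = TRUE` (two groups, at most 10,000 distinct assignments) all
#' distinct group assignments are enumerated and the p-value is the exact
#' fraction with a statistic at least as large as observed.
#'
#' @param d a [stats::dist] or distance matrix.
#' @param labels group label per sample (matrix order).
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all distinct assignments instead of sampling.
#' @return An object of class `virome_permanova` with `statistic`
#'   (pseudo-F), `R2`, `p_value`, `df`, `n_perm`, `method`.
#' @export
permanova <- function(d, labels, n_perm = 9999, seed = 1,
                      exhaustive = FALSE) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  n <- nrow(m)
  if (length(labels) != n) abort("labels must match the distance matrix")
  tab <- table(labels)
  if (length(tab) < 2) abort("PERMANOVA needs at least 2 groups")
  if (any(tab < 2)) abort("every group needs at least 2 samples")
  d2 <- m^2

  f_stat <- function(lab) {
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    a <- length(unique(lab))
    list(f = (ss_between / (a - 1)) / (ss_within / (n - a)),
         r2 = ss_between / ss_total)
  }

  obs <- f_stat(labels)

  if (exhaustive) {
    if (length(tab) != 2) abort("exhaustive enumeration supports 2 groups")
    g1 <- names(tab)[1]
    n1 <- tab[[1]]
    balanced <- length(unique(tab)) == 1
    combos <- if (balanced) {
      # fix sample 1 in group 1 so each unordered bipartition appears once
      lapply(utils::combn(2:n, n1 - 1, simplify = FALSE),
             function(x) c(1L, x))
    } else {
      utils::combn(seq_len(n), n1, simplify = FALSE)
    }
    if (length(combos) > 10000) {
      abort("too many assignments for exhaustive enumeration")
    }
    fs <- vapply(combos, function(idx) {
      lab <- rep(names(tab)[2], n)
      lab[idx] <- g1
      f_stat(lab)$f
    }, numeric(1))
    p <- sum(fs >= obs$f - 1e-12) / length(fs)
    n_used <- length(fs)
    method <- "PERMANOVA (exhaustive)"
  } else {
    fs <- with_seed(derive_seed(seed, "permanova"), {
      vapply(seq_len(n_perm), function(i) {
        f_stat(sample(labels))$f
      }, numeric(1))
    })
    p <- (sum(fs >= obs$f - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
    method <- "PERMANOVA"
  }

  structure(
    list(statistic = obs$f, R2 = obs$r2, p_value = p,
         df = c(between = length(tab) - 1, within = n - length(tab)),
         n_perm = n_used, method = method),
    class = "virome_permanova"
  )
}

#' Procrustes randomization test between two ordinations
#'
#' Superimposes two sample configurations (symmetric Procrustes: both
#' centred and scaled to unit trace on their common first k axes), computes
#' the residual statistic `m2 = 1 - (sum of singular values)^2` and the
#' correlation `r = sqrt(1 - m2)`, and obtains a p-value by permuting the
#' rows of the second configuration.
#'
#' @param x,y `virome_pcoa` objects, or matrices/tibbles of coordinates with
#'   sample ids (rownames or a `sample_id` column).
#' @param n_perm number of row permutations (default 9999).
#' @param seed integer seed.
#' @return An object of class `virome_procrustes` with `m2`, `r`,
#'   `p_value`, `n_perm`.
#' @export
procrustes_test <- function(x, y, n_perm = 9999, seed = 1) {
  xm <- coord_matrix(x)
  ym <- coord_matrix(y)
  if (nrow(xm) < 3) abort("Procrustes needs at least 3 samples")
  if (!setequal(rownames(xm), rownames(ym))) {
    abort("sample ids of the two configurations do not match")
  }
  ym <- ym[rownames(xm), , drop = FALSE]
  k <- min(ncol(xm), ncol(ym))
  xm <- normalize_config(xm[, seq_len(k), drop = FALSE])
  ym <- normalize_config(ym[, seq_len(k), drop = FALSE])

  m2_of <- function(a, b) {
    max(0, 1 - sum(svd(crossprod(a, b))$d)^2)
  }
  m2 <- m2_of(xm, ym)

  exceed <- with_seed(derive_seed(seed, "procrustes"), {
    sum(vapply(seq_len(n_perm), function(i) {
      m2_of(xm, ym[sample(nrow(ym)), , drop = FALSE]) <= m2 + 1e-12
    }, logical(1)))
  })
  structure(
    list(m2 = m2, r = sqrt(1 - m2), p_value = (exceed + 1) / (n_perm + 1),
         n_perm = n_perm, method = "Procrustes randomization test"),
    class = "virome_procrustes"
  )
}

coord_matrix <- function(x) {
  if (inherits(x, "virome_pcoa")) {
    m <- as.matrix(x$coordinates[-1])
    rownames(m) <- x$coordinates$sample_id
    return(m)
  }
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) {
      m <- as.matrix(x[setdiff(names(x), "sample_id")])
      rownames(m) <- x$sample_id
      return(m)
    }
    return(as.matrix(x))
  }
  as.matrix(x)
}

normalize_config <- function(m) {
  m <- scale(m, center = TRUE, scale = FALSE)
  m / sqrt(sum(m^2))
}

#' Distribution-gated two-group and multi-group comparison
#'
#' Applies the test-selection rule used throughout the analyses: residual
#' normality (Shapiro-Wilk) and variance homogeneity (Levene) are checked at
#' alpha = 0.05; two groups are compared by a two-tailed t-test when both
#' hold and by the Wilcoxon-Mann-Whitney test otherwise; more than two
#' groups by ANOVA with Tukey's post hoc (two-way when a second factor is
#' supplied) when both hold, and by Kruskal-Wallis with Dunn's post hoc
#' otherwise.
#'
#' @param values numeric response.
#' @param labels primary grouping factor.
#' @param labels2 optional second crossed factor (two-way designs).
#' @param gate_alpha alpha for the normality/homoscedasticity gates.
#' @return A list of class `virome_test`: `method`, `statistic`, `p_value`,
#'   `normality_p`, `levene_p`, `posthoc` (tibble or `NULL`).
#' @export
group_compare <- function(values, labels, labels2 = NULL,
                          gate_alpha = 0.05) {
  labels <- factor(labels)
  if (any(table(labels) < 2)) abort("every group needs at least 2 values")
  centers <- tapply(values, labels, mean)
  residuals <- values - centers[labels]
  normality_p <- tryCatch(shapiro.test(residuals)$p.value,
                          error = function(e) 0)
  levene_p <- levene_p_value(values, labels)
  parametric <- normality_p >= gate_alpha && levene_p >= gate_alpha
  n_groups <- nlevels(labels)

  if (n_groups == 2) {
    if (parametric) {
      ht <- t.test(values ~ labels, var.equal = TRUE)
      method <- "t-test"
    } else {
      ht <- suppressWarnings(wilcox.test(values ~ labels))
      method <- "wilcoxon"
    }
    # fully tied data carries no evidence against the null
    p <- if (is.nan(ht$p.value)) 1 else ht$p.value
    res <- list(method = method, statistic = unname(ht$statistic),
                p_value = p, posthoc = NULL)
  } else if (parametric) {
    df <- data.frame(y = values, g = labels)
    fit <- if (!is.null(labels2)) {
      df$g2 <- factor(labels2)
      aov(y ~ g * g2, data = df)
    } else {
      aov(y ~ g, data = df)
    }
    sm <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    res <- list(method = if (is.null(labels2)) "anova" else "two-way anova",
                statistic = sm$`F value`[1], p_value = sm$`Pr(>F)`[1],
                posthoc = tibble(comparison = rownames(tk),
                                 diff = tk[, "diff"],
                                 p_adj = tk[, "p adj"]))
  } else {
    kw <- kruskal.test(values, labels)
    res <- list(method = "kruskal-wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                posthoc = dunn_test(values, labels))
  }
  structure(c(res, list(normality_p = normality_p, levene_p = levene_p)),
            class = "virome_test")
}

levene_p_value <- function(values, labels) {
  if (requireNamespace("car", quietly = TRUE)) {
    out <- tryCatch(
      car::leveneTest(values ~ labels)[["Pr(>F)"]][1],
      error = function(e) NA_real_)
    if (!is.na(out)) return(out)
  }
  # Brown-Forsythe: ANOVA on absolute deviations from group medians
  med <- tapply(values, labels, median)
  z <- abs(values - med[labels])
  if (sd(z) == 0) return(1)
  summary(aov(z ~ labels))[[1]][["Pr(>F)"]][1]
}

#' Dunn's post hoc test
#'
#' Pairwise z tests on mean ranks after a Kruskal-Wallis test, with tie
#' correction and p-value adjustment across pairs.
#'
#' @param values numeric response.
#' @param labels grouping factor.
#' @param p_adjust_method method for [stats::p.adjust] (default BH).
#' @return A tibble `comparison`, `z`, `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, labels, p_adjust_method = "BH") {
  labels <- factor(labels)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, labels, mean)
  sizes <- table(labels)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    z <- (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se
    tibble(comparison = paste(p, collapse = "-"), z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  out$p_adj <- p.adjust(out$p_value, method = p_adjust_method)
  out
}

#' Batch correlations with FDR control
#'
#' Computes a correlation test for every pair in the batch and adjusts the
#' p-values with Benjamini-Hochberg across the batch. Pairs with a
#' zero-variance member get `NA` estimates and are flagged.
#'
#' @param pairs a tibble with columns `pair` (identifier), `x`, `y`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble `pair`, `n`, `estimate`, `p_value`, `q_value`,
#'   `flagged`.
#' @export
correlate_fdr <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_columns(pairs, c("pair", "x", "y"))
  out <- pairs |>
    group_by(.data$pair) |>
    summarise(
      n = sum(complete.cases(.data$x, .data$y)),
      estimate = {
        ok <- complete.cases(.data$x, .data$y)
        if (sum(ok) < 3 || sd(.data$x[ok]) == 0 || sd(.data$y[ok]) == 0) {
          NA_real_
        } else {
          suppressWarnings(cor(.data$x[ok], .data$y[ok], method = method))
        }
      },
      p_value = {
        ok <- complete.cases(.data$x, .data$y)
        if (sum(ok) < 3 || sd(.data$x[ok]) == 0 || sd(.data$y[ok]) == 0) {
          NA_real_
        } else {
          suppressWarnings(
            cor.test(.data$x[ok], .data$y[ok], method = method)$p.value)
        }
      },
      .groups = "drop"
    ) |>
    mutate(flagged = is.na(.data$estimate))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  select(out, "pair", "n", "estimate", "p_value", "q_value", "flagged")
}
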