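#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols across n distinct
#'   rename pull if_else row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats rnorm rbinom rlnorm rpois setNames median quantile sd var
#'   p.adjust pnorm pt cor cor.test t.test wilcox.test shapiro.test
#'   kruskal.test aov TukeyHSD complete.cases as.dist
#' @importFrom utils combn head
NULL

# Round half away from zero (documented rounding rule for depth -> counts;
# base round() is banker's rounding and would map 2.5 -> 2).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Format a percentage to one decimal, half-up, as a number (82.2 not "82.2%").
percent_1dp <- function(part, total) {
  if (total == 0) return(0)
  round_half_up(100 * part / total * 10) / 10
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647L)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
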