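#' Read and write pipeline tables
#'
#' Plain-text interchange formats used between stages: gene annotation TSV
#' (`contig_id`, `gene_id`, `start`, `end`, `strand`, `category`, `label`),
#' coverage TSV modeled on the `samtools coverage` column set (`feature_id`,
#' `sample_id`, `assay`, `length`, `covered_bases`, `breadth`, `mean_depth`),
#' and sample metadata TSV (`sample_id`, `mouse_id`, `group`, `assay`).
#'
#' @param path file path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name pipeline_io
NULL

annotation_cols <- c("contig_id", "gene_id", "start", "end", "strand",
                     "category", "label")
coverage_cols <- c("feature_id", "sample_id", "assay", "length",
                   "covered_bases", "breadth", "mean_depth")
metadata_cols <- c("sample_id", "mouse_id", "group", "assay")

#' @rdname pipeline_io
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(tbl, annotation_cols, "annotation table")
  tbl
}

#' @rdname pipeline_io
#' @param annotations annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(annotations, annotation_cols, "annotations")
  readr::write_tsv(annotations[annotation_cols], path)
  invisible(annotations)
}

#' @rdname pipeline_io
#' @export
read_coverage <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(tbl, coverage_cols, "coverage table")
  bad <- tbl$covered_bases > tbl$length
  if (any(bad)) {
    abort(sprintf("covered_bases exceeds length for feature(s): %s",
                  paste(unique(tbl$feature_id[bad]), collapse = ", ")))
  }
  tbl
}

#' @rdname pipeline_io
#' @param coverage coverage tibble.
#' @export
write_coverage <- function(coverage, path) {
  assert_columns(coverage, coverage_cols, "coverage")
  readr::write_tsv(coverage[coverage_cols], path)
  invisible(coverage)
}

#' @rdname pipeline_io
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(tbl, metadata_cols, "metadata table")
  tbl
}

# Minimal FASTA writer/reader via Biostrings when available; the sequences
# handled here are plain character vectors.
write_fasta <- function(seqs, path, width = 80) {
  seqs <- seqs[!is.na(seqs)]
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    ids <- sub("^>", "", lines[idx])
    grp <- cumsum(idx)
    seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1),
                   collapse = "")
    setNames(unname(seqs), ids)
  }
}

#' Write or read a feature table with its sidecar metadata
#'
#' Feature tables travel as TSV (features in rows, samples in columns) with a
#' sidecar JSON holding the table kind and construction parameters.
#'
#' @param table a `virome_feature_table`.
#' @param path TSV path; the sidecar is written next to it as `<path>.json`.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(table, path)
  meta <- list(kind = attr(table, "kind"),
               min_samples = attr(table, "min_samples"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(tbl, "kind") <- meta$kind
    attr(tbl, "min_samples") <- meta$min_samples
  }
  class(tbl) <- c("virome_feature_table", class(tbl))
  tbl
}
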