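#' Read guide/target pairs from a two-column CSV
#'
#' @param path CSV with columns `guide` and `target` (21-nt strings).
#' @param modifications Modifications applied to every guide (list of
#'   [modification_spec()]), or `NULL`.
#' @return List of [guide_target_pair()] objects.
#' @export
read_pairs_csv <- function(path, modifications = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("guide", "target") %in% names(df))) {
    stop("pairs CSV must have columns 'guide' and 'target'")
  }
  lapply(seq_len(nrow(df)), function(k) {
    guide_target_pair(df$guide[k], df$target[k], modifications)
  })
}

#' Read a log2 fold-change table from CSV
#'
#' @param path CSV with columns `gene_id`, `log2fc` and optionally
#'   `mean_expression`.
#' @return data.frame with those columns.
#' @export
read_log2fc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df))) {
    stop("log2FC CSV must have columns 'gene_id' and 'log2fc'")
  }
  df
}

#' Write a feature table to Parquet or CSV
#'
#' The format follows the file extension: `.parquet` (requires the `arrow`
#' package) or anything else as CSV. Labels are written as a final `label`
#' column.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$features, label = table$labels)
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("writing Parquet requires the 'arrow' package")
    }
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path `.parquet` or CSV file with feature columns and a final
#'   `label` column.
#' @param variant Optional variant tag to attach.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, variant = NULL) {
  df <- if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path)
  }
  if (!"label" %in% names(df)) stop("no 'label' column in ", path)
  feature_table(df[setdiff(names(df), "label")], df$label, variant = variant)
}
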