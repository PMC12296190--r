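#' Select the most highly expressed genes
#'
#' Keeps the top `fraction` of genes by mean expression (count rounded up),
#' the standard pre-filter before computing off-target labels: lowly
#' expressed genes have unreliable fold-change estimates. Ties at the cutoff
#' are broken by gene-id lexicographic order so the selection is
#' deterministic.
#'
#' @param mean_expression Named numeric vector, gene id -> mean expression.
#' @param fraction Fraction of genes to keep (default 0.2).
#' @return Character vector of selected gene ids.
#' @export
select_top_genes <- function(mean_expression, fraction = 0.2) {
  if (length(mean_expression) == 0L) stop("empty expression map")
  if (is.null(names(mean_expression)) || any(names(mean_expression) == "")) {
    stop("mean_expression must be named by gene id")
  }
  if (any(!is.finite(mean_expression))) stop("non-finite expression values")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(mean_expression))
  ord <- order(-mean_expression, names(mean_expression))
  names(mean_expression)[ord][seq_len(k)]
}

#' Binarize log2 fold changes into off-target labels
#'
#' Label 1 (off-target) where the absolute log2 fold change strictly exceeds
#' the threshold; label 0 otherwise. A value exactly at the threshold is
#' negative.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param threshold Positive threshold (default 0.25).
#' @return Integer 0/1 vector.
#' @export
binarize_labels <- function(log2fc, threshold = 0.25) {
  if (any(!is.finite(log2fc))) stop("log2fc contains non-finite values")
  stopifnot(threshold > 0)
  as.integer(abs(log2fc) > threshold)
}

#' Feature table: named feature matrix plus binary labels
#'
#' The interface between feature generation and the evaluation harness: one
#' row per siRNA-gene pair, named numeric feature columns, and a binary
#' label vector.
#'
#' @param features data.frame (or matrix) of numeric features, no missing
#'   values.
#' @param labels Integer/numeric 0/1 vector, one per row.
#' @param variant Optional dataset-variant tag (e.g. `"D3"`).
#' @return An object of class `feature_table` with components `features`,
#'   `labels`, `variant`.
#' @export
feature_table <- function(features, labels, variant = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop("feature table must be non-empty")
  }
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric")
  }
  if (anyNA(features)) stop("feature table contains missing values")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop("row-count mismatch: ", nrow(features), " feature rows vs ",
         length(labels), " labels")
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1")
  }
  structure(list(features = features, labels = labels, variant = variant),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table", if (!is.null(x$variant)) paste0("[", x$variant, "]"),
      ">", nrow(x$features), "rows x", ncol(x$features), "features;",
      sum(x$labels), "positive labels\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

# expected widths for the sequence-only variants; structural variants'
# widths depend on the configured residue match set
.variant_widths <- c(D2 = 42L, D3 = 1344L, D4 = 99L)

# assemble displacement tables (one per row) into a feature matrix
.displacement_block <- function(tables, include_rna) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  tabs <- lapply(tables, function(t) {
    if (!include_rna) t <- t[t$kind == "protein", , drop = FALSE]
    t
  })
  keys <- tabs[[1L]]$residue
  rows <- lapply(tabs, function(t) {
    if (!identical(sort(t$residue), sort(keys))) {
      stop("displacement tables do not share a residue key set")
    }
    t$displacement[match(keys, t$residue)]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("disp_", keys)
  m
}

# per-pair modification fingerprint block (96 bytes)
.modification_block <- function(pairs, library) {
  rows <- lapply(pairs, function(p) {
    kinds <- vapply(p$modifications, function(m) m$kind, character(1))
    dimer <- if ("AMIDE_DIMER" %in% kinds) library$AG_amide_dimer else
      library$AG_dimer
    mono <- if ("GNA_MONOMER" %in% kinds) library$GNA_U else library$U
    modification_fingerprints(dimer, mono)
  })
  do.call(rbind, rows)
}

#' Assemble one of the nine dataset variants
#'
#' Builds the named feature representation from its component blocks and
#' attaches labels. Variants follow the study's numbering (there are no
#' variants 5 or 8):
#' \describe{
#'   \item{D0}{96 compressed modification-fingerprint bytes + protein-residue
#'     displacements from trajectory-derived structures.}
#'   \item{D1}{Full representative-atom x/y/z coordinates per residue
#'     (3 per residue).}
#'   \item{D2}{Simple numeric encoding of guide + target (42 features).}
#'   \item{D3}{Positional per-nucleotide circular fingerprints of guide +
#'     target (21 x 32 x 2 = 1344 features).}
#'   \item{D4}{Gene-index byte triple + the 96 modification-fingerprint
#'     bytes (99 features).}
#'   \item{D6N/D6R}{Displacements versus the pre-modeling base structure,
#'     RNA residues included; `R` applies 0-255 column rescaling.}
#'   \item{D7N/D7R}{Displacements versus the experimental reference, protein
#'     residues only; `R` applies 0-255 column rescaling.}
#' }
#'
#' Column order within a variant is fixed: guide block, target block,
#' gene-index block, fingerprint block, structural block.
#'
#' @param variant One of `"D0"`, `"D1"`, `"D2"`, `"D3"`, `"D4"`, `"D6N"`,
#'   `"D6R"`, `"D7N"`, `"D7R"`.
#' @param labels Binary labels, one per row.
#' @param pairs List of [guide_target_pair()] (variants D0, D2, D3, D4).
#' @param gene_ids Character vector of Ensembl ids (variant D4).
#' @param structures List of [complex_structure()] models (variant D1).
#' @param displacement_tables List of `displacement_table`s, one per row
#'   (variants D0, D6N, D6R, D7N, D7R).
#' @param library A [monomer_library()]; built once if not supplied.
#' @return A [feature_table()].
#' @export
build_dataset <- function(variant, labels, pairs = NULL, gene_ids = NULL,
                          structures = NULL, displacement_tables = NULL,
                          library = NULL) {
  variant <- match.arg(variant,
                       c("D0", "D1", "D2", "D3", "D4", "D6N", "D6R",
                         "D7N", "D7R"))
  needs_lib <- variant %in% c("D0", "D3", "D4")
  if (needs_lib && is.null(library)) library <- monomer_library()

  feats <- switch(
    variant,
    D2 = {
      stopifnot(!is.null(pairs))
      do.call(rbind, lapply(pairs, encode_simple))
    },
    D3 = {
      stopifnot(!is.null(pairs))
      do.call(rbind, lapply(pairs, function(p) {
        c(positional_fingerprints(
            strand_graphs(p$guide, p$modifications, library),
            prefix = "fpg"),
          positional_fingerprints(
            strand_graphs(p$target, list(), library), prefix = "fpt"))
      }))
    },
    D4 = {
      stopifnot(!is.null(pairs), !is.null(gene_ids))
      if (length(gene_ids) != length(pairs)) {
        stop("join error: ", length(pairs), " pairs vs ",
             length(gene_ids), " gene ids")
      }
      idx <- t(vapply(gene_ids, encode_gene_id, integer(3)))
      cbind(idx, .modification_block(pairs, library))
    },
    D0 = {
      stopifnot(!is.null(pairs), !is.null(displacement_tables))
      if (length(displacement_tables) != length(pairs)) {
        stop("join error: pairs vs displacement tables")
      }
      cbind(.modification_block(pairs, library),
            .displacement_block(displacement_tables, include_rna = FALSE))
    },
    D1 = {
      stopifnot(!is.null(structures))
      do.call(rbind, lapply(structures, extract_coordinates))
    },
    D6N = .displacement_block(displacement_tables, include_rna = TRUE),
    D6R = rescale_columns(
      .displacement_block(displacement_tables, include_rna = TRUE)),
    D7N = .displacement_block(displacement_tables, include_rna = FALSE),
    D7R = rescale_columns(
      .displacement_block(displacement_tables, include_rna = FALSE))
  )

  feats <- as.data.frame(feats)
  expected <- .variant_widths[variant]
  if (!is.na(expected) && ncol(feats) != expected) {
    stop("assembly error: variant ", variant, " produced ", ncol(feats),
         " features, expected ", expected)
  }
  feature_table(feats, labels, variant = variant)
}
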