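#' Guide/target pair with chemical modification annotations
#'
#' Represents one siRNA guide strand (21 nt, 5'->3') together with its aligned
#' intended mRNA target region (21 nt, stored 5'->3' of the mRNA) and any
#' chemical modifications on the guide. The supported modifications mirror a
#' common therapeutic design: an amide-linked dinucleotide replacing the
#' internucleotide phosphate at guide positions 3-4, and a glycol nucleic acid
#' (GNA) monomer at guide position 7.
#'
#' @param guide 21-character string over the alphabet `A`, `C`, `G`, `U`.
#' @param target 21-character string over the same alphabet.
#' @param modifications List of [modification_spec()] objects (possibly empty).
#'
#' @return An object of class `guide_target_pair`.
#' @examples
#' p <- guide_target_pair(strrep("A", 21), strrep("U", 21))
#' encode_simple(p)
#' @export
guide_target_pair <- function(guide, target, modifications = list()) {
  guide <- .check_strand(guide, "guide")
  target <- .check_strand(target, "target")
  if (inherits(modifications, "modification_spec")) {
    modifications <- list(modifications)
  }
  stopifnot(is.list(modifications))
  for (m in modifications) {
    if (!inherits(m, "modification_spec")) {
      stop("modifications must be modification_spec objects")
    }
  }
  structure(list(guide = guide, target = target,
                 modifications = modifications),
            class = "guide_target_pair")
}

.strand_alphabet <- c("A", "C", "G", "U")

.check_strand <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string")
  }
  x <- toupper(x)
  if (nchar(x) != 21L) {
    stop(what, " must be exactly 21 nucleotides, got ", nchar(x))
  }
  chars <- strsplit(x, "")[[1L]]
  bad <- setdiff(unique(chars), .strand_alphabet)
  if (length(bad) > 0L) {
    stop("invalid nucleotide(s) in ", what, ": ", paste(bad, collapse = ", "))
  }
  x
}

#' Chemical modification annotation
#'
#' @param kind One of `"AMIDE_DIMER"` (amide-linked dinucleotide spanning two
#'   adjacent guide positions) or `"GNA_MONOMER"` (glycol nucleic acid
#'   monomer at a single position).
#' @param positions 1-based guide positions: exactly two adjacent positions
#'   for a dimer, one position for a monomer. Defaults follow the design
#'   studied here: dimer at 3-4, monomer at 7.
#' @return An object of class `modification_spec`.
#' @export
modification_spec <- function(kind = c("AMIDE_DIMER", "GNA_MONOMER"),
                              positions = NULL) {
  kind <- match.arg(kind)
  if (is.null(positions)) {
    positions <- if (kind == "AMIDE_DIMER") c(3L, 4L) else 7L
  }
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > 21L)) {
    stop("modification positions must lie in 1..21")
  }
  if (kind == "AMIDE_DIMER") {
    if (length(positions) != 2L || diff(positions) != 1L) {
      stop("AMIDE_DIMER occupies exactly two adjacent positions")
    }
  } else if (length(positions) != 1L) {
    stop("GNA_MONOMER occupies exactly one position")
  }
  structure(list(kind = kind, positions = positions),
            class = "modification_spec")
}

#' Simple numeric encoding of a guide/target pair
#'
#' Encodes the 21-nt guide followed by the 21-nt target as integers:
#' A = 1, C = 2, G = 3, U = 4. On the guide, an amide dimer's two positions
#' carry codes 5 (5'-side member) and 6 (3'-side member) and a GNA monomer
#' position carries 7, overriding the base code. Target positions always use
#' base codes. This is the 42-feature "simple encoding" dataset variant.
#'
#' @param pair A [guide_target_pair()].
#' @return Named integer vector of length 42 (`g01..g21`, `t01..t21`),
#'   values in 1..7.
#' @export
encode_simple <- function(pair) {
  stopifnot(inherits(pair, "guide_target_pair"))
  base_code <- function(s) {
    match(strsplit(s, "")[[1L]], .strand_alphabet)
  }
  g <- base_code(pair$guide)
  t <- base_code(pair$target)
  for (m in pair$modifications) {
    if (m$kind == "AMIDE_DIMER") {
      g[m$positions[1L]] <- 5L
      g[m$positions[2L]] <- 6L
    } else if (m$kind == "GNA_MONOMER") {
      g[m$positions[1L]] <- 7L
    }
  }
  out <- as.integer(c(g, t))
  names(out) <- c(sprintf("g%02d", 1:21), sprintf("t%02d", 1:21))
  out
}

#' 24-bit byte encoding of an Ensembl gene identifier
#'
#' Strips the `ENSG` prefix and leading zeros from an Ensembl gene identifier
#' and splits the remaining integer `n` (< 2^24) into three unsigned bytes:
#' the most significant byte `(n >> 16) & 0xFF`, the middle byte
#' `(n >> 8) & 0xFF` and the least significant byte `n & 0xFF`. Because
#' Ensembl identifiers are assigned roughly sequentially, the high-order
#' bytes implicitly group related genes.
#'
#' Identifiers with version suffixes (e.g. `".14"`) are rejected rather than
#' truncated, so the encoding is bit-exact and reversible.
#'
#' @param ensembl_id Single identifier string, `ENSG` followed by digits.
#' @return Named integer vector `c(gene_idx0, gene_idx1, gene_idx2)`, each
#'   in 0..255.
#' @seealso [decode_gene_index()] for the inverse.
#' @examples
#' encode_gene_id("ENSG00000000419")  # c(0, 1, 163)
#' @export
encode_gene_id <- function(ensembl_id) {
  if (!is.character(ensembl_id) || length(ensembl_id) != 1L ||
      is.na(ensembl_id)) {
    stop("ensembl_id must be a single string")
  }
  if (!grepl("^ENSG[0-9]+$", ensembl_id)) {
    stop("malformed Ensembl identifier: ", ensembl_id)
  }
  digits <- sub("^ENSG", "", ensembl_id)
  n <- as.numeric(digits)  # leading zeros drop on numeric conversion
  if (n >= 2^24) {
    stop("numeric portion ", format(n, scientific = FALSE),
         " does not fit in 24 bits")
  }
  out <- c(gene_idx0 = (n %/% 65536) %% 256,
           gene_idx1 = (n %/% 256) %% 256,
           gene_idx2 = n %% 256)
  storage.mode(out) <- "integer"
  out
}

#' Reconstruct the integer from a gene-index byte triple
#'
#' @param triple Integer vector of length 3 (`gene_idx0`, `gene_idx1`,
#'   `gene_idx2`), each in 0..255.
#' @return The reconstructed integer `idx0*65536 + idx1*256 + idx2`.
#' @export
decode_gene_index <- function(triple) {
  triple <- as.numeric(triple)
  if (length(triple) != 3L || any(!is.finite(triple)) ||
      any(triple < 0 | triple > 255) || any(triple != floor(triple))) {
    stop("triple must be three integers in 0..255")
  }
  triple[1L] * 65536 + triple[2L] * 256 + triple[3L]
}

#' Encode a vector of Ensembl identifiers as a byte-triple table
#'
#' @param ids Character vector of Ensembl gene identifiers.
#' @return data.frame with columns `gene_id`, `gene_idx0`, `gene_idx1`,
#'   `gene_idx2`.
#' @export
encode_gene_table <- function(ids) {
  stopifnot(is.character(ids), length(ids) >= 1L)
  m <- t(vapply(ids, encode_gene_id, integer(3)))
  data.frame(gene_id = ids, gene_idx0 = m[, 1L], gene_idx1 = m[, 2L],
             gene_idx2 = m[, 3L], row.names = NULL)
}
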