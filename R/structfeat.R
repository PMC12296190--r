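#' Residue-level representation of an RNA-protein complex
#'
#' Stores one representative atom per residue — C-alpha for protein residues,
#' C1' for RNA residues — which is the resolution at which superposition and
#' displacement features operate.
#'
#' @param residues data.frame with columns `chain` (character), `resno`
#'   (integer), `resname` (character), `kind` (`"protein"` or `"rna"`), and
#'   coordinates `x`, `y`, `z` in Angstrom.
#' @return An object of class `complex_structure`.
#' @export
complex_structure <- function(residues) {
  residues <- as.data.frame(residues)
  need <- c("chain", "resno", "resname", "kind", "x", "y", "z")
  if (!all(need %in% names(residues))) {
    stop("residues must have columns: ", paste(need, collapse = ", "))
  }
  residues <- residues[need]
  residues$chain <- as.character(residues$chain)
  residues$resno <- as.integer(residues$resno)
  residues$resname <- as.character(residues$resname)
  residues$kind <- as.character(residues$kind)
  if (!all(residues$kind %in% c("protein", "rna"))) {
    stop("kind must be 'protein' or 'rna'")
  }
  coords <- as.matrix(residues[c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  key <- paste(residues$chain, residues$resno, sep = "_")
  if (anyDuplicated(key)) stop("duplicate (chain, resno) residue keys")
  rownames(residues) <- NULL
  structure(list(residues = residues), class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  tab <- table(x$residues$kind)
  cat("<complex_structure>", nrow(x$residues), "residues (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
  invisible(x)
}

.residue_keys <- function(s) {
  paste(s$residues$chain, s$residues$resno, sep = "_")
}

.coord_matrix <- function(s) {
  m <- as.matrix(s$residues[c("x", "y", "z")])
  rownames(m) <- .residue_keys(s)
  m
}

#' Read a complex from a PDB file at residue resolution
#'
#' Extracts one representative atom per residue: `CA` for amino-acid
#' residues, `C1'` for nucleic-acid residues. Residues lacking their
#' representative atom are dropped.
#'
#' @param path Path to a PDB file.
#' @return A [complex_structure()].
#' @export
read_complex_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  rna_res <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
               "ADE", "CYT", "GUA", "URA")
  is_ca <- at$elety == "CA" & !(at$resid %in% rna_res)
  is_c1 <- at$elety %in% c("C1'", "C1*") & at$resid %in% rna_res
  sel <- at[is_ca | is_c1, ]
  if (nrow(sel) == 0L) stop("no CA/C1' representative atoms found in ", path)
  complex_structure(data.frame(
    chain = sel$chain, resno = sel$resno, resname = sel$resid,
    kind = ifelse(sel$elety == "CA", "protein", "rna"),
    x = sel$x, y = sel$y, z = sel$z))
}

#' Write a complex to a PDB file (one representative atom per residue)
#'
#' @param structure A [complex_structure()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_complex_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "complex_structure"))
  r <- structure$residues
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(r[c("x", "y", "z")]))),
    resno = r$resno, chain = r$chain, resid = r$resname,
    elety = ifelse(r$kind == "protein", "CA", "C1'"))
  invisible(path)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Superposes the model onto the reference over their matched residues
#' (shared `(chain, resno)` keys by default, optionally restricted to protein
#' residues), using the Kabsch algorithm: the optimal proper rotation is
#' obtained from the SVD of the cross-covariance of the centered coordinate
#' sets, with a reflection correction so that `det(R) = +1`.
#'
#' @param model,reference [complex_structure()] objects.
#' @param selection Optional character vector of residue keys
#'   (`"<chain>_<resno>"`) to fit on; default: all shared keys.
#' @param protein_only If `TRUE`, fit only on protein residues (default
#'   `TRUE`, mirroring a global C-alpha fit).
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (post-fit, Angstrom), `n_fit` (atoms fitted), and `model_fitted`
#'   (the full model with transformed coordinates). Fitted coordinates are
#'   `R %*% (x - centroid_model) + centroid_reference`.
#' @export
superpose <- function(model, reference, selection = NULL,
                      protein_only = TRUE) {
  stopifnot(inherits(model, "complex_structure"),
            inherits(reference, "complex_structure"))
  mk <- .residue_keys(model)
  rk <- .residue_keys(reference)
  shared <- intersect(mk, rk)
  if (protein_only) {
    prot <- .residue_keys(model)[model$residues$kind == "protein"]
    shared <- intersect(shared, prot)
  }
  if (!is.null(selection)) shared <- intersect(shared, selection)
  if (length(shared) < 3L) {
    stop("superposition needs at least 3 matched residues, got ",
         length(shared))
  }
  P <- .coord_matrix(model)[shared, , drop = FALSE]
  Q <- .coord_matrix(reference)[shared, , drop = FALSE]

  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)            # 3x3 cross-covariance
  s <- svd(H)
  if (s$d[2L] < 1e-8 * max(s$d[1L], 1)) {
    stop("degenerate (collinear) coordinates: superposition ill-conditioned")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)

  fitted_sel <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))

  all_xyz <- .coord_matrix(model)
  fitted_all <- sweep(all_xyz, 2L, cp) %*% t(R)
  fitted_all <- sweep(fitted_all, 2L, cq, FUN = "+")
  model_fitted <- model
  model_fitted$residues[c("x", "y", "z")] <- fitted_all

  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd = rmsd, n_fit = length(shared), model_fitted = model_fitted)
}

#' Per-residue displacements of a fitted model versus a reference
#'
#' For each residue matched by `(chain, resno)` between an already-superposed
#' model and the reference, computes the Euclidean distance between the
#' representative atoms. These displacements are the structural features of
#' the displacement-based dataset variants; RNA residues are included only
#' when requested (the experimental reference lacks many RNA residues, so
#' protein-only tables mirror that situation).
#'
#' @param model A [complex_structure()], typically `superpose(...)$model_fitted`.
#' @param reference A [complex_structure()].
#' @param include_rna Include RNA residues shared with the reference
#'   (default `FALSE`).
#' @param reference_id Identifier of the reference structure, stored as an
#'   attribute on the result (e.g. `"4f3t"` or `"base"`).
#' @return A `displacement_table`: data.frame with columns `residue`
#'   (key `"<chain>_<resno>"`), `kind`, `displacement` (Angstrom, >= 0),
#'   with the reference id in `attr(, "reference")`.
#' @export
residue_displacements <- function(model, reference, include_rna = FALSE,
                                  reference_id = "reference") {
  stopifnot(inherits(model, "complex_structure"),
            inherits(reference, "complex_structure"))
  mk <- .residue_keys(model)
  rk <- .residue_keys(reference)
  shared <- intersect(mk, rk)
  if (length(shared) == 0L) stop("no residues shared between model and reference")
  kind <- model$residues$kind[match(shared, mk)]
  if (!include_rna) {
    keep <- kind == "protein"
    shared <- shared[keep]
    kind <- kind[keep]
  }
  P <- .coord_matrix(model)[shared, , drop = FALSE]
  Q <- .coord_matrix(reference)[shared, , drop = FALSE]
  out <- data.frame(residue = shared, kind = kind,
                    displacement = sqrt(rowSums((P - Q)^2)),
                    row.names = NULL)
  attr(out, "reference") <- reference_id
  class(out) <- c("displacement_table", "data.frame")
  out
}

#' Superpose then extract displacement features in one call
#'
#' @inheritParams residue_displacements
#' @return A `displacement_table` (see [residue_displacements()]).
#' @export
displacement_features <- function(model, reference, include_rna = FALSE,
                                  reference_id = "reference") {
  fit <- superpose(model, reference)
  residue_displacements(fit$model_fitted, reference,
                        include_rna = include_rna,
                        reference_id = reference_id)
}

#' Flat residue-coordinate feature vector
#'
#' Concatenates the representative-atom x, y, z of every residue in residue
#' order: 3 features per residue (an 879-residue complex yields 2637).
#'
#' @param model A [complex_structure()].
#' @return Named numeric vector of length `3 * n_residues`
#'   (`<chain>_<resno>_x` etc.).
#' @export
extract_coordinates <- function(model) {
  stopifnot(inherits(model, "complex_structure"))
  m <- .coord_matrix(model)
  out <- as.numeric(t(m))
  names(out) <- paste(rep(rownames(m), each = 3L), c("x", "y", "z"),
                      sep = "_")
  out
}

#' Rescale feature columns to unsigned-byte range
#'
#' Per column, maps values linearly so the column minimum becomes 0 and the
#' maximum 255, rounding half away from zero; constant columns map to 0.
#' Used by the rescaled structural dataset variants to put displacement
#' features on a common scale.
#'
#' @param table Numeric matrix or data.frame.
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
rescale_columns <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("table must be numeric")
  if (!all(is.finite(m))) stop("non-finite values in feature table")
  out <- apply(m, 2L, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) return(rep(0L, length(v)))
    as.integer(floor(255 * (v - min(v)) / rng + 0.5))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Replicate reproducibility metric: sum of relative standard deviations
#'
#' Quantifies the consistency of a structure-generation pipeline across
#' replicate runs from the same starting point. For each protein residue the
#' relative standard deviation of its displacement across replicates is
#' computed (sample standard deviation divided by the mean; residues with
#' zero mean contribute 0), and the values are summed over residues. Lower
#' is more reproducible; identical replicates score exactly 0, and the
#' metric is invariant to a common rescaling of all displacements.
#'
#' @param replicates List of `n >= 2` `displacement_table`s from independent
#'   runs, sharing an identical residue key set.
#' @return Non-negative number.
#' @export
sigma_rsd <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("need at least 2 replicate displacement tables")
  }
  tabs <- lapply(replicates, function(t) {
    stopifnot(inherits(t, "displacement_table") || is.data.frame(t))
    t[t$kind == "protein", , drop = FALSE]
  })
  keys <- tabs[[1L]]$residue
  for (t in tabs[-1L]) {
    if (!identical(sort(t$residue), sort(keys))) {
      stop("replicates must share an identical residue key set")
    }
  }
  disp <- matrix(unlist(lapply(tabs, function(t) {
    t$displacement[match(keys, t$residue)]
  })), nrow = length(keys))
  rsd <- apply(disp, 1L, function(v) {
    m <- mean(v)
    if (m == 0) 0 else stats::sd(v) / m
  })
  sum(rsd)
}
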