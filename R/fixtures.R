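#' Fixture generator configuration
#'
#' Bundles the parameters of the synthetic data generators that stand in for
#' the experimental inputs: an RNA-Seq-derived log2 fold-change table, guide
#' siRNA / target pairs, and replicate modeled structures.
#'
#' @param n_pairs Number of siRNA-gene pairs to generate.
#' @param prevalence Expected positive-label fraction after binarizing
#'   log2 fold changes at |log2FC| > 0.25. Default 0.29, a realistic
#'   off-target class imbalance for a genome-wide knockdown screen.
#' @param sigma Per-atom Gaussian coordinate noise for structure replicates,
#'   in Angstrom.
#' @param deformation Scale (Angstrom) of the fixed model-versus-reference
#'   deformation shared by all replicates of a starting point; emulates the
#'   systematic difference between a modeled complex and the experimental
#'   reference it is aligned to. Set to 0 for replicates that are exact
#'   rigid copies of the reference.
#' @param n_protein,n_rna Protein and RNA residue counts of the toy complex.
#' @param n_replicates Number of structure replicates per starting point.
#' @param seed RNG seed; every generator is deterministic given the seed.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_pairs = 200L, prevalence = 0.29, sigma = 0.1,
                           deformation = 0.5, n_protein = 52L, n_rna = 8L,
                           n_replicates = 10L, seed = 1L) {
  stopifnot(n_pairs >= 1L, prevalence > 0, prevalence < 1, sigma >= 0,
            deformation >= 0, n_protein >= 3L, n_rna >= 0L,
            n_replicates >= 1L)
  structure(list(n_pairs = as.integer(n_pairs), prevalence = prevalence,
                 sigma = sigma, deformation = deformation,
                 n_protein = as.integer(n_protein),
                 n_rna = as.integer(n_rna),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# -- monomer chemistry ------------------------------------------------------

# build a monomer_graph from named atoms and name-pair bonds
.graph_from_names <- function(atoms, bonds, name = NULL) {
  els <- unname(atoms)
  idx <- stats::setNames(seq_along(atoms), names(atoms))
  b <- do.call(rbind, lapply(bonds, function(bd) {
    c(idx[[bd[[1L]]]], idx[[bd[[2L]]]],
      if (length(bd) >= 3L) as.integer(bd[[3L]]) else 1L)
  }))
  monomer_graph(els, b, name = name)
}

# ribose + 5'-phosphate backbone; glycosidic bond left to the base builder
.ribose_phosphate <- function(suffix = "") {
  s <- function(x) paste0(x, suffix)
  atoms <- stats::setNames(
    c("P", "O", "O", "O", "O", "C", "C", "O", "C", "O", "C", "O", "C"),
    s(c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'", "C3'",
        "O3'", "C2'", "O2'", "C1'")))
  bonds <- list(
    list(s("P"), s("OP1"), 2L), list(s("P"), s("OP2")),
    list(s("P"), s("OP3")), list(s("P"), s("O5'")),
    list(s("O5'"), s("C5'")), list(s("C5'"), s("C4'")),
    list(s("C4'"), s("O4'")), list(s("O4'"), s("C1'")),
    list(s("C4'"), s("C3'")), list(s("C3'"), s("O3'")),
    list(s("C3'"), s("C2'")), list(s("C2'"), s("O2'")),
    list(s("C2'"), s("C1'")))
  list(atoms = atoms, bonds = bonds)
}

# base atom/bond sets (Kekule structures); attach = glycosidic nitrogen
.base_defs <- list(
  A = list(
    atoms = c(N9 = "N", C8 = "C", N7 = "N", C5 = "C", C6 = "C", N6 = "N",
              N1 = "N", C2 = "C", N3 = "N", C4 = "C"),
    bonds = list(list("N9", "C4"), list("C4", "C5", 2L), list("C5", "N7"),
                 list("N7", "C8", 2L), list("C8", "N9"), list("C5", "C6"),
                 list("C6", "N1", 2L), list("N1", "C2"),
                 list("C2", "N3", 2L), list("N3", "C4"), list("C6", "N6")),
    attach = "N9"),
  G = list(
    atoms = c(N9 = "N", C8 = "C", N7 = "N", C5 = "C", C6 = "C", O6 = "O",
              N1 = "N", C2 = "C", N2 = "N", N3 = "N", C4 = "C"),
    bonds = list(list("N9", "C4"), list("C4", "C5", 2L), list("C5", "N7"),
                 list("N7", "C8", 2L), list("C8", "N9"), list("C5", "C6"),
                 list("C6", "O6", 2L), list("C6", "N1"), list("N1", "C2"),
                 list("C2", "N3", 2L), list("N3", "C4"), list("C2", "N2")),
    attach = "N9"),
  C = list(
    atoms = c(N1 = "N", C2 = "C", O2 = "O", N3 = "N", C4 = "C", N4 = "N",
              C5 = "C", C6 = "C"),
    bonds = list(list("N1", "C2"), list("C2", "O2", 2L), list("C2", "N3"),
                 list("N3", "C4", 2L), list("C4", "N4"), list("C4", "C5"),
                 list("C5", "C6", 2L), list("C6", "N1")),
    attach = "N1"),
  U = list(
    atoms = c(N1 = "N", C2 = "C", O2 = "O", N3 = "N", C4 = "C", O4 = "O",
              C5 = "C", C6 = "C"),
    bonds = list(list("N1", "C2"), list("C2", "O2", 2L), list("C2", "N3"),
                 list("N3", "C4"), list("C4", "O4", 2L), list("C4", "C5"),
                 list("C5", "C6", 2L), list("C6", "N1")),
    attach = "N1")
)

# nucleoside-5'-monophosphate graph for base b
.nmp_graph <- function(b, name = b) {
  bb <- .ribose_phosphate()
  base <- .base_defs[[b]]
  atoms <- c(bb$atoms, base$atoms)
  bonds <- c(bb$bonds, base$bonds, list(list("C1'", base$attach)))
  .graph_from_names(atoms, bonds, name = name)
}

# AG dinucleotide: A-5'-monophosphate linked 3'->5' to a G nucleoside,
# either through a phosphodiester or an amide (C(=O)-NH) linkage
.ag_dimer_graph <- function(amide = FALSE) {
  a <- .ribose_phosphate("")
  baseA <- .base_defs$A
  atomsA <- c(a$atoms, stats::setNames(unname(baseA$atoms),
                                       paste0(names(baseA$atoms), "a")))
  bondsA <- c(a$bonds,
              lapply(baseA$bonds, function(bd) {
                c(list(paste0(bd[[1L]], "a"), paste0(bd[[2L]], "a")),
                  if (length(bd) >= 3L) bd[3L])
              }),
              list(list("C1'", paste0(baseA$attach, "a"))))

  # G nucleoside part (no 5'-phosphate of its own)
  sg <- function(x) paste0(x, "g")
  atomsG_bb <- stats::setNames(
    c("O", "C", "C", "O", "C", "O", "C", "O", "C"),
    sg(c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")))
  bondsG_bb <- list(
    list(sg("O5'"), sg("C5'")), list(sg("C5'"), sg("C4'")),
    list(sg("C4'"), sg("O4'")), list(sg("O4'"), sg("C1'")),
    list(sg("C4'"), sg("C3'")), list(sg("C3'"), sg("O3'")),
    list(sg("C3'"), sg("C2'")), list(sg("C2'"), sg("O2'")),
    list(sg("C2'"), sg("C1'")))
  baseG <- .base_defs$G
  atomsG <- c(atomsG_bb, stats::setNames(unname(baseG$atoms),
                                         paste0(names(baseG$atoms), "gb")))
  bondsG <- c(bondsG_bb,
              lapply(baseG$bonds, function(bd) {
                c(list(paste0(bd[[1L]], "gb"), paste0(bd[[2L]], "gb")),
                  if (length(bd) >= 3L) bd[3L])
              }),
              list(list(sg("C1'"), paste0(baseG$attach, "gb"))))

  if (amide) {
    # amide internucleotide linkage: C3'(A)-C(=O)-N(H)-C5'(G);
    # replaces O3'(A), the bridging phosphate, and O5'(G)
    atomsA <- atomsA[names(atomsA) != "O3'"]
    bondsA <- Filter(function(bd) !any(unlist(bd[1:2]) == "O3'"), bondsA)
    atomsG <- atomsG[names(atomsG) != sg("O5'")]
    bondsG <- Filter(function(bd) !any(unlist(bd[1:2]) == sg("O5'")), bondsG)
    link_atoms <- c(Cam = "C", Oam = "O", Nam = "N")
    link_bonds <- list(list("C3'", "Cam"), list("Cam", "Oam", 2L),
                       list("Cam", "Nam"), list("Nam", sg("C5'")))
  } else {
    link_atoms <- c(P2 = "P", O2P1 = "O", O2P2 = "O")
    link_bonds <- list(list("O3'", "P2"), list("P2", "O2P1", 2L),
                       list("P2", "O2P2"), list("P2", sg("O5'")))
  }
  .graph_from_names(c(atomsA, link_atoms, atomsG),
                    c(bondsA, link_bonds, bondsG),
                    name = if (amide) "AG_amide_dimer" else "AG_dimer")
}

# glycol nucleic acid uridine: acyclic three-carbon backbone with a
# 5'-phosphate, uracil on the central carbon
.gna_u_graph <- function() {
  atoms <- c(P = "P", OP1 = "O", OP2 = "O", OP3 = "O", O3g = "O",
             C3g = "C", C2g = "C", C1g = "C", O1g = "O")
  bonds <- list(list("P", "OP1", 2L), list("P", "OP2"), list("P", "OP3"),
                list("P", "O3g"), list("O3g", "C3g"), list("C3g", "C2g"),
                list("C2g", "C1g"), list("C1g", "O1g"))
  base <- .base_defs$U
  .graph_from_names(c(atoms, base$atoms),
                    c(bonds, base$bonds, list(list("C2g", base$attach))),
                    name = "GNA_U")
}

#' Library of nucleotide monomer and dimer graphs
#'
#' Heavy-atom connectivity graphs for the chemical building blocks used by
#' the fingerprint features: the four ribonucleoside-5'-monophosphates, an
#' AG dinucleotide (phosphodiester-linked), its amide-linked counterpart, a
#' glycol-nucleic-acid uridine, and an all-carbon copy of the guanosine
#' monophosphate topology for the progressive-substitution demonstration.
#' Only connectivity, elements, charges and bond orders matter at the small
#' fingerprint radii used here, so literature coordinates are not required.
#'
#' @return Named list of [monomer_graph()] objects: `A`, `C`, `G`, `U`,
#'   `AG_dimer`, `AG_amide_dimer`, `GNA_U`, `guanosine_allC`.
#' @export
monomer_library <- function() {
  g <- .nmp_graph("G")
  all_c <- monomer_graph(rep("C", n_atoms(g)), g$bonds,
                         name = "guanosine_allC")
  list(A = .nmp_graph("A"), C = .nmp_graph("C"), G = g, U = .nmp_graph("U"),
       AG_dimer = .ag_dimer_graph(FALSE),
       AG_amide_dimer = .ag_dimer_graph(TRUE),
       GNA_U = .gna_u_graph(),
       guanosine_allC = all_c)
}

#' Substitution series completing guanosine from its all-carbon skeleton
#'
#' Ordered atom substitutions that convert the all-carbon guanosine
#' monophosphate skeleton into the true structure, beginning with the central
#' backbone phosphorus and ending with the ring nitrogens of the base.
#' Carbon positions are included as explicit no-op rows, so the series
#' visits every atom once.
#'
#' @return data.frame with columns `index` (atom index in the skeleton) and
#'   `element` (true element symbol), one row per atom.
#' @export
guanosine_substitutions <- function() {
  g <- .nmp_graph("G")
  els <- g$elements
  # phosphorus first, then remaining atoms in graph order
  p <- which(els == "P")
  ord <- c(p, setdiff(seq_along(els), p))
  data.frame(index = ord, element = els[ord])
}

# -- strand graphs ----------------------------------------------------------

#' Per-position monomer graphs for a 21-nt strand
#'
#' Maps each strand position to its monomer graph from the library. A GNA
#' monomer modification substitutes the glycol-U graph at its position; an
#' amide-dimer modification substitutes the amide-linked AG dimer graph at
#' both of its positions (the dimer is the chemical unit spanning them).
#'
#' @param sequence 21-character strand string (`A`, `C`, `G`, `U`).
#' @param modifications List of [modification_spec()] objects (guide strands
#'   only; pass `list()` for targets).
#' @param library A [monomer_library()] (pass explicitly to amortize
#'   construction over many strands).
#' @return List of 21 [monomer_graph()] objects.
#' @export
strand_graphs <- function(sequence, modifications = list(),
                          library = monomer_library()) {
  sequence <- .check_strand(sequence, "sequence")
  chars <- strsplit(sequence, "")[[1L]]
  graphs <- library[chars]
  for (m in modifications) {
    if (m$kind == "GNA_MONOMER") {
      graphs[[m$positions[1L]]] <- library$GNA_U
    } else if (m$kind == "AMIDE_DIMER") {
      graphs[[m$positions[1L]]] <- library$AG_amide_dimer
      graphs[[m$positions[2L]]] <- library$AG_amide_dimer
    }
  }
  unname(graphs)
}

# -- structures -------------------------------------------------------------

#' Deterministic toy RNA-protein reference complex
#'
#' A helical C-alpha trace for the protein chain (chain A) plus a short
#' helical C1' trace for the RNA chain (chain B). Purely geometric: it gives
#' superposition and displacement code a realistic shape (non-planar,
#' non-degenerate) at desk scale.
#'
#' @param n_protein Protein residue count (chain A).
#' @param n_rna RNA residue count (chain B).
#' @return A [complex_structure()] with `n_protein + n_rna` residues.
#' @export
make_reference_complex <- function(n_protein = 52L, n_rna = 8L) {
  stopifnot(n_protein >= 3L, n_rna >= 0L)
  i <- seq_len(n_protein)
  prot <- data.frame(chain = "A", resno = i, resname = "ALA",
                     kind = "protein",
                     x = 2.3 * cos(i * 100 * pi / 180),
                     y = 2.3 * sin(i * 100 * pi / 180),
                     z = 1.5 * i)
  res <- prot
  if (n_rna > 0L) {
    j <- seq_len(n_rna)
    rna <- data.frame(chain = "B", resno = j, resname = "U", kind = "rna",
                      x = 9.0 * cos(j * 32 * pi / 180) + 6,
                      y = 9.0 * sin(j * 32 * pi / 180) - 4,
                      z = 2.8 * j + 10)
    res <- rbind(prot, rna)
  }
  complex_structure(res)
}

# random proper rotation matrix
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

# apply rigid motion + optional per-residue Gaussian noise to a structure
.perturb_structure <- function(s, sigma = 0) {
  xyz <- as.matrix(s$residues[c("x", "y", "z")])
  R <- .random_rotation()
  t <- stats::rnorm(3, sd = 20)
  xyz <- sweep(xyz %*% t(R), 2L, t, FUN = "+")
  if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma),
                                     ncol = 3L)
  out <- s
  out$residues[c("x", "y", "z")] <- xyz
  out
}

#' Replicate modeled structures around a toy reference
#'
#' Emulates replicate runs of a structure-generation pipeline from the same
#' starting point. A fixed per-residue deformation of scale `deformation`
#' (drawn once per seed) is applied to the reference to play the role of the
#' systematic model-versus-reference difference; each replicate is that
#' deformed model under an independent random rigid motion plus per-residue
#' Gaussian coordinate noise of scale `sigma`. After superposition the
#' displacements have mean set by the deformation and replicate scatter set
#' by `sigma`, so the reproducibility metric responds to the noise level:
#' with `sigma = 0` all replicates are identical and the metric is 0.
#'
#' @param config A [fixture_config()]; uses `n_protein`, `n_rna`,
#'   `n_replicates`, `sigma`, `deformation`, `seed`.
#' @return List with `reference` (a [complex_structure()]) and `replicates`
#'   (list of `n_replicates` complex structures).
#' @export
make_structure_replicates <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  ref <- make_reference_complex(config$n_protein, config$n_rna)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  model <- ref
  if (config$deformation > 0) {
    xyz <- as.matrix(model$residues[c("x", "y", "z")])
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = config$deformation),
                        ncol = 3L)
    model$residues[c("x", "y", "z")] <- xyz
  }
  reps <- lapply(seq_len(config$n_replicates), function(k) {
    .perturb_structure(model, config$sigma)
  })
  list(reference = ref, replicates = reps)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# -- labels -----------------------------------------------------------------

#' Synthetic log2 fold-change label table
#'
#' Draws per-gene log2 fold changes from a two-component mixture: null genes
#' from Normal(0, 0.08) and off-target genes from a sign-symmetric
#' Normal(0.5, 0.15), with the mixture weight solved so that the expected
#' positive fraction after binarization at |log2FC| > 0.25 equals the
#' configured prevalence. Gene identifiers are valid Ensembl-format strings
#' with 24-bit numeric portions; mean expression counts are log-normal.
#'
#' @param config A [fixture_config()]; uses `n_pairs`, `prevalence`, `seed`.
#' @return data.frame with columns `gene_id`, `log2fc`, `mean_expression`.
#' @export
make_label_table <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  p_null <- 2 * stats::pnorm(-0.25 / 0.08)
  p_off <- stats::pnorm(-0.25, 0.5, 0.15) + 1 - stats::pnorm(0.25, 0.5, 0.15)
  w <- (config$prevalence - p_null) / (p_off - p_null)
  if (w < 0 || w > 1) {
    stop("prevalence ", config$prevalence,
         " is unreachable with the configured mixture components")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_pairs
  ids <- sprintf("ENSG%011.0f", sample.int(2^24 - 1L, n))
  off <- stats::runif(n) < w
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  l2fc <- ifelse(off, sgn * stats::rnorm(n, 0.5, 0.15),
                 stats::rnorm(n, 0, 0.08))
  data.frame(gene_id = ids, log2fc = l2fc,
             mean_expression = stats::rlnorm(n, meanlog = 5, sdlog = 1.5))
}

# -- guide/target pairs -----------------------------------------------------

#' Synthetic guide/target pairs
#'
#' Random 21-nt guides with their fully complementary mRNA target regions
#' (target stored 5'->3' of the mRNA, i.e. the reverse complement of the
#' guide). A configurable fraction of guides carries the studied chemical
#' modifications (amide dimer at positions 3-4 plus GNA monomer at 7).
#'
#' @param n Number of pairs.
#' @param modified_fraction Fraction of guides carrying modifications.
#' @param seed RNG seed.
#' @return List of [guide_target_pair()] objects.
#' @export
make_guide_target_pairs <- function(n, modified_fraction = 0.5, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  lapply(seq_len(n), function(k) {
    guide <- sample(.strand_alphabet, 21L, replace = TRUE)
    target <- rev(unname(comp[guide]))
    mods <- if (stats::runif(1) < modified_fraction) {
      list(modification_spec("AMIDE_DIMER"), modification_spec("GNA_MONOMER"))
    } else list()
    guide_target_pair(paste(guide, collapse = ""),
                      paste(target, collapse = ""), mods)
  })
}

#' Sequence-labelled synthetic classification set
#'
#' Guide/target pairs whose binary label depends on guide sequence content
#' (G+C count in the seed region, positions 2-8, with a small label-flip
#' noise), so that sequence-derived feature representations carry real
#' signal. Used to compare feature representations on equal footing.
#'
#' @param n Number of pairs.
#' @param flip Label-noise probability.
#' @param seed RNG seed.
#' @return List with `pairs` (list of [guide_target_pair()]) and `labels`
#'   (integer 0/1 vector).
#' @export
make_sequence_labelled_set <- function(n, flip = 0.1, seed = 1L) {
  pairs <- make_guide_target_pairs(n, modified_fraction = 0.5, seed = seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  labels <- vapply(pairs, function(p) {
    seed_region <- strsplit(substr(p$guide, 2L, 8L), "")[[1L]]
    as.integer(sum(seed_region %in% c("G", "C")) >= 4L)
  }, integer(1))
  flipped <- stats::runif(n) < flip
  labels[flipped] <- 1L - labels[flipped]
  list(pairs = pairs, labels = labels)
}
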