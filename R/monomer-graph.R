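#' Molecular graph of a nucleotide monomer or dimer
#'
#' A `monomer_graph` is the heavy-atom molecular graph used for circular
#' fingerprinting: a list of atoms (element symbol, formal charge) and a list
#' of bonds (atom index pairs with integer bond order). Hydrogens are not
#' represented; only connectivity, elements, charges and bond orders matter
#' for fingerprints at small radius.
#'
#' @param elements Character vector of element symbols (e.g. `"C"`, `"N"`,
#'   `"O"`, `"P"`). One entry per heavy atom.
#' @param bonds Two- or three-column matrix (or data.frame) of bonds: columns
#'   `i`, `j` are 1-based atom indices, optional column `order` is the integer
#'   bond order (default 1).
#' @param charges Integer vector of formal charges, recycled to the number of
#'   atoms. Default 0.
#' @param name Optional name for the graph (used for caching and printing).
#' @param position Optional 1-based strand position label.
#'
#' @return An object of class `monomer_graph` with components `elements`,
#'   `charges`, `bonds` (data.frame with columns `i`, `j`, `order`), `name`
#'   and `position`.
#'
#' @examples
#' # carbon monoxide-like toy: two atoms, one double bond
#' g <- monomer_graph(c("C", "O"), cbind(1, 2, 2))
#' n_atoms(g)
#' @export
monomer_graph <- function(elements, bonds, charges = 0L, name = NULL,
                          position = NULL) {
  stopifnot(is.character(elements), length(elements) >= 1L)
  unknown <- setdiff(unique(elements), names(.atomic_numbers))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(elements)
  charges <- as.integer(rep_len(charges, n))

  if (is.null(dim(bonds))) bonds <- matrix(bonds, ncol = length(bonds))
  bonds <- as.data.frame(bonds)
  if (ncol(bonds) == 2L) bonds$order <- 1L
  names(bonds) <- c("i", "j", "order")
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.integer(bonds$order)
  if (n > 1L && nrow(bonds) == 0L) stop("multi-atom graph requires bonds")
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("bond atom index out of range")
    }
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$order < 1L)) stop("bond order must be >= 1")
    # canonical endpoint order, for stable serialization
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  }

  g <- structure(
    list(elements = elements, charges = charges, bonds = bonds,
         name = name, position = position),
    class = "monomer_graph"
  )
  if (!.is_connected(g)) stop("molecular graph must be connected")
  g
}

#' Number of heavy atoms in a monomer graph
#' @param g A [monomer_graph()].
#' @return Integer atom count.
#' @export
n_atoms <- function(g) {
  stopifnot(inherits(g, "monomer_graph"))
  length(g$elements)
}

#' @export
print.monomer_graph <- function(x, ...) {
  cat("<monomer_graph", if (!is.null(x$name)) paste0("'", x$name, "'"),
      ">", length(x$elements), "atoms,", nrow(x$bonds), "bonds\n")
  cat("  formula:", paste(names(tab <- table(x$elements)), tab,
                          sep = "", collapse = " "), "\n")
  invisible(x)
}

#' Permute atom indices of a monomer graph
#'
#' Renumbers atoms according to `perm` (atom `k` becomes atom `perm[k]`),
#' producing a graph of the same molecule. Circular fingerprints are invariant
#' under this operation.
#'
#' @param g A [monomer_graph()].
#' @param perm A permutation of `seq_len(n_atoms(g))`.
#' @return A `monomer_graph` for the same molecule with renumbered atoms.
#' @export
permute_atoms <- function(g, perm) {
  stopifnot(inherits(g, "monomer_graph"))
  n <- n_atoms(g)
  if (length(perm) != n || !setequal(perm, seq_len(n))) {
    stop("perm must be a permutation of 1..n_atoms")
  }
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  elements <- g$elements
  charges <- g$charges
  elements[perm] <- g$elements
  charges[perm] <- g$charges
  bonds <- g$bonds
  bonds$i <- perm[g$bonds$i]
  bonds$j <- perm[g$bonds$j]
  monomer_graph(elements, bonds, charges, name = g$name,
                position = g$position)
}

#' Replace the element of selected atoms
#'
#' Used by the progressive-substitution fingerprint demonstration: the
#' topology and bond orders are untouched, only element identities change.
#'
#' @param g A [monomer_graph()].
#' @param indices Atom indices to modify.
#' @param elements Replacement element symbols (recycled).
#' @return The modified `monomer_graph`.
#' @export
substitute_elements <- function(g, indices, elements) {
  stopifnot(inherits(g, "monomer_graph"))
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > n_atoms(g))) {
    stop("substitution atom index out of range")
  }
  el <- g$elements
  el[indices] <- rep_len(elements, length(indices))
  monomer_graph(el, g$bonds, g$charges, name = g$name, position = g$position)
}

.atomic_numbers <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                     S = 16L, Cl = 17L, Br = 35L, I = 53L)

# adjacency list: for each atom, data.frame(nbr, order, bond)
.adjacency <- function(g) {
  n <- length(g$elements)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- list(nbr = integer(0), order = integer(0),
                                         bond = integer(0))
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
    adj[[i]]$order <- c(adj[[i]]$order, o)
    adj[[i]]$bond <- c(adj[[i]]$bond, k)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
    adj[[j]]$order <- c(adj[[j]]$order, o)
    adj[[j]]$bond <- c(adj[[j]]$bond, k)
  }
  adj
}

.is_connected <- function(g) {
  n <- length(g$elements)
  if (n == 1L) return(TRUE)
  adj <- .adjacency(g)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[a]]$nbr
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}
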