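#' Circular fingerprint configuration
#'
#' @param n_bits Folded fingerprint length in bits (positive; must be a
#'   multiple of 8 if the fingerprint will be byte-packed).
#' @param radius Number of neighborhood-growing iterations (non-negative).
#' @return An object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(n_bits, radius) {
  n_bits <- as.integer(n_bits)
  radius <- as.integer(radius)
  stopifnot(length(n_bits) == 1L, n_bits > 0L,
            length(radius) == 1L, radius >= 0L)
  structure(list(n_bits = n_bits, radius = radius),
            class = "fingerprint_config")
}

# 32-bit FNV-1a over a vector of non-negative integers (< 2^32), each
# consumed as 4 little-endian bytes. Pure double arithmetic; all
# intermediates stay well below 2^53.
.fnv1a <- function(ints) {
  h <- 2166136261
  p <- 16777619
  for (v in ints) {
    v <- as.numeric(v)
    for (shift in c(1, 256, 65536, 16777216)) {
      byte <- (v %/% shift) %% 256
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(byte))
      lo <- h %% 65536
      hi <- h %/% 65536
      h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
    }
  }
  h
}

#' Circular (extended-connectivity) fingerprint of a molecular graph
#'
#' Implements the standard circular-fingerprint construction: every atom
#' receives an initial integer identifier hashed from its invariants (atomic
#' number, heavy-atom degree, formal charge, summed bond orders); identifiers
#' are then iteratively updated up to `radius` rounds by hashing the previous
#' identifier together with the sorted (bond order, neighbor identifier)
#' pairs. Each identifier marks one bit at position `id mod n_bits`.
#' Duplicate atom environments (identical bond sets) yield a single
#' identifier — the smallest hash among the duplicates — so the output is
#' deterministic and invariant under atom renumbering.
#'
#' @param mol A [monomer_graph()].
#' @param config A [fingerprint_config()].
#' @return Integer 0/1 vector of length `config$n_bits`.
#' @export
circular_fingerprint <- function(mol, config) {
  stopifnot(inherits(mol, "monomer_graph"),
            inherits(config, "fingerprint_config"))
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule")
  # memoized on graph content: the function is pure and repeated monomers
  # dominate strand-level featurization
  key <- paste(config$n_bits, config$radius,
               paste(mol$elements, collapse = ""),
               paste(mol$charges, collapse = ","),
               paste(mol$bonds$i, mol$bonds$j, mol$bonds$order,
                     collapse = ";"),
               sep = "|")
  cached <- .fp_cache[[key]]
  if (!is.null(cached)) return(cached)
  ids <- .environment_identifiers(mol, config$radius)
  bits <- integer(config$n_bits)
  bits[(ids %% config$n_bits) + 1L] <- 1L
  .fp_cache[[key]] <- bits
  bits
}

.fp_cache <- new.env(parent = emptyenv())

# All deduplicated environment identifiers up to `radius`.
.environment_identifiers <- function(mol, radius) {
  n <- n_atoms(mol)
  adj <- .adjacency(mol)
  ids_prev <- vapply(seq_len(n), function(a) {
    .fnv1a(c(.atomic_numbers[[mol$elements[a]]],
             length(adj[[a]]$nbr),
             mol$charges[a] + 128,       # keep non-negative
             sum(adj[[a]]$order)))
  }, numeric(1))

  identifiers <- ids_prev                   # radius-0 ids are always kept
  seen_envs <- character(0)
  env_prev <- rep(list(integer(0)), n)
  alive <- rep(TRUE, n)

  for (r in seq_len(radius)) {
    if (!any(alive)) break
    ids_new <- ids_prev
    env_new <- env_prev
    cand_key <- character(0)
    cand_hash <- numeric(0)
    for (a in which(alive)) {
      env <- .bonds_within(a, r, adj)
      if (identical(env, env_prev[[a]])) {
        alive[a] <- FALSE                   # environment stopped growing
        next
      }
      nb <- adj[[a]]$nbr
      o <- order(adj[[a]]$order, ids_prev[nb])
      payload <- c(r, ids_prev[a],
                   as.numeric(rbind(adj[[a]]$order[o], ids_prev[nb[o]])))
      h <- .fnv1a(payload)
      ids_new[a] <- h
      env_new[[a]] <- env
      cand_key <- c(cand_key, paste(env, collapse = ","))
      cand_hash <- c(cand_hash, h)
    }
    if (length(cand_key) > 0L) {
      keep <- !(cand_key %in% seen_envs)
      if (any(keep)) {
        # one identifier per distinct environment: smallest hash wins,
        # so the choice does not depend on atom numbering
        picked <- tapply(cand_hash[keep], cand_key[keep], min)
        identifiers <- c(identifiers, as.numeric(picked))
        seen_envs <- c(seen_envs, names(picked))
      }
    }
    ids_prev <- ids_new
    env_prev <- env_new
  }
  identifiers
}

# sorted indices of bonds with both endpoints within `r` hops of atom a
.bonds_within <- function(a, r, adj) {
  dist <- rep(NA_integer_, length(adj))
  dist[a] <- 0L
  frontier <- a
  for (d in seq_len(r)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- adj[[v]]$nbr
      new <- nb[is.na(dist[nb])]
      dist[new] <- d
      nxt <- c(nxt, new)
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  inside <- which(!is.na(dist))
  bonds <- unique(unlist(lapply(inside, function(v) {
    sel <- adj[[v]]$nbr %in% inside
    adj[[v]]$bond[sel]
  })))
  sort(bonds)
}

#' Pack a binary vector into unsigned bytes (big-endian)
#'
#' Compresses a 0/1 vector whose length is a multiple of 8 into unsigned
#' 8-bit integers, most significant bit first: byte `k` is
#' `sum(bit[8k+j] * 2^(7-j))` for `j = 0..7`. A 512-bit fingerprint packs to
#' 64 byte-features, a 256-bit fingerprint to 32.
#'
#' @param bits Integer/logical vector of 0s and 1s, length divisible by 8.
#' @return Integer vector of bytes in 0..255, length `length(bits) / 8`,
#'   with class `compressed_fp`.
#' @seealso [unpack_bytes()] for the exact inverse.
#' @examples
#' compress_bits(c(1, 0, 0, 0, 0, 0, 0, 1))  # 129
#' @export
compress_bits <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) %% 8L != 0L) {
    stop("bit vector length must be divisible by 8, got ", length(bits))
  }
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stop("bits must contain only 0 and 1")
  }
  m <- matrix(bits, nrow = 8L)
  bytes <- as.integer(colSums(m * 2^(7:0)))
  structure(bytes, class = "compressed_fp")
}

#' Unpack bytes back into the source bit vector
#'
#' @param bytes Integer vector of values in 0..255 (e.g. a `compressed_fp`).
#' @return Integer 0/1 vector of length `8 * length(bytes)`.
#' @export
unpack_bytes <- function(bytes) {
  bytes <- as.integer(unclass(bytes))
  if (any(is.na(bytes)) || any(bytes < 0L | bytes > 255L)) {
    stop("bytes must be integers in 0..255")
  }
  as.integer(vapply(bytes, function(b) as.integer((b %/% 2^(7:0)) %% 2),
                    integer(8)))
}

#' Compressed modification fingerprints (dimer + monomer block)
#'
#' Fingerprints the dinucleotide unit at guide positions 3-4 (unmodified AG
#' or amide-linked AG) with 512 bits at radius 2, and the position-7 monomer
#' (U or GNA-U) with 256 bits at radius 1, then byte-packs both: 64 + 32 =
#' 96 byte features describing the chemical modification state of the guide.
#'
#' @param dimer [monomer_graph()] of the position 3-4 dinucleotide.
#' @param monomer [monomer_graph()] of the position-7 monomer.
#' @return Named integer vector of 96 bytes
#'   (`fp_dimer_00..63`, `fp_monomer_00..31`).
#' @export
modification_fingerprints <- function(dimer, monomer) {
  d <- compress_bits(circular_fingerprint(dimer, fingerprint_config(512, 2)))
  m <- compress_bits(circular_fingerprint(monomer, fingerprint_config(256, 1)))
  out <- c(unclass(d), unclass(m))
  names(out) <- c(sprintf("fp_dimer_%02d", 0:63),
                  sprintf("fp_monomer_%02d", 0:31))
  out
}

#' Positional per-nucleotide fingerprints of one strand
#'
#' Treats each of the 21 strand positions as an independent monomer and
#' fingerprints it with a small circular fingerprint (default 32 bits,
#' radius 1). The raw bits are the features — 21 x 32 = 672 per strand; a
#' guide plus its target region yields 1344.
#'
#' @param monomers List of exactly 21 [monomer_graph()] objects in strand
#'   order (5'->3').
#' @param config [fingerprint_config()]; default 32 bits, radius 1.
#' @param prefix Feature-name prefix (default `"fp"`).
#' @return Named integer 0/1 vector of length `21 * n_bits`
#'   (`<prefix>_<pos>_<bit>`).
#' @export
positional_fingerprints <- function(monomers,
                                    config = fingerprint_config(32, 1),
                                    prefix = "fp") {
  if (!is.list(monomers) || length(monomers) != 21L) {
    stop("need exactly 21 monomer graphs, got ", length(monomers))
  }
  cache <- new.env(parent = emptyenv())
  rows <- lapply(monomers, function(g) {
    stopifnot(inherits(g, "monomer_graph"))
    key <- g$name
    if (!is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
    fp <- circular_fingerprint(g, config)
    if (!is.null(key)) cache[[key]] <- fp
    fp
  })
  out <- unlist(rows, use.names = FALSE)
  names(out) <- as.vector(t(outer(
    sprintf("%s_%02d", prefix, 1:21),
    sprintf("%02d", seq_len(config$n_bits) - 1L), paste, sep = "_")))
  out
}

#' Progressive atom-substitution fingerprint series
#'
#' Demonstrates how circular fingerprints respond to chemistry: starting from
#' an all-carbon copy of a monomer's topology, atoms are substituted one at a
#' time with their true elements (conventionally beginning with the backbone
#' phosphorus) and the compressed fingerprint is recorded after each step.
#' Substituting a carbon for a carbon is a no-op and leaves the fingerprint
#' row unchanged; ring-completing heteroatoms change many byte positions.
#'
#' @param skeleton [monomer_graph()] with the target topology, all elements
#'   typically `"C"`.
#' @param substitutions data.frame (or 2-column matrix) with columns `index`
#'   (atom index) and `element` (replacement symbol), applied in row order.
#' @param config [fingerprint_config()]; default 256 bits, radius 1.
#' @return Integer matrix with `nrow(substitutions) + 1` rows and
#'   `n_bits / 8` columns; row 1 is the skeleton, row `i + 1` the structure
#'   after the first `i` substitutions.
#' @export
progressive_substitution <- function(skeleton, substitutions,
                                     config = fingerprint_config(256, 1)) {
  stopifnot(inherits(skeleton, "monomer_graph"))
  if (config$n_bits %% 8L != 0L) stop("n_bits must be divisible by 8")
  substitutions <- as.data.frame(substitutions)
  if (nrow(substitutions) > 0L) {
    names(substitutions) <- c("index", "element")
  }
  n_rows <- nrow(substitutions) + 1L
  out <- matrix(0L, nrow = n_rows, ncol = config$n_bits %/% 8L,
                dimnames = list(paste0("step", seq_len(n_rows) - 1L),
                                sprintf("fp_byte_%02d",
                                        seq_len(config$n_bits %/% 8L) - 1L)))
  current <- skeleton
  out[1L, ] <- unclass(compress_bits(circular_fingerprint(current, config)))
  for (k in seq_len(nrow(substitutions))) {
    current <- substitute_elements(current, substitutions$index[k],
                                   substitutions$element[k])
    out[k + 1L, ] <- unclass(compress_bits(circular_fingerprint(current,
                                                                config)))
  }
  out
}
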