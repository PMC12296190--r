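# Independent oracles used to cross-check package computations.

# Brute-force average precision: recomputes the confusion counts from
# scratch at every distinct threshold (O(n^2)) and applies the step-wise
# definition sum((R_i - R_{i-1}) * P_i). Independent of the package's
# sort/cumsum implementation path.
brute_average_precision <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  prev_r <- 0
  ap <- 0
  for (th in ths) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / pos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# Trapezoidal integration of the precision-recall curve, recomputing the
# confusion counts from scratch at every distinct threshold. Deliberately
# naive (O(n^2)); independent of the package's step-wise estimator.
trapezoid_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(ths, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    c(p = if (tp + fp == 0) 1 else tp / (tp + fp),
      r = tp / sum(labels == 1))
  }, numeric(2)))
  r <- c(0, pr[, "r"])
  p <- c(pr[1, "p"], pr[, "p"])
  sum(diff(r) * (p[-length(p)] + p[-1]) / 2)
}

# big-endian packing of one byte, written as the plain arithmetic definition
pack_byte_naive <- function(bits8) sum(bits8 * 2^(7:0))

# a small non-degenerate complex used across structural tests
toy_complex <- function(n = 12L) {
  make_reference_complex(n_protein = n, n_rna = 0L)
}

# apply a fixed rigid motion (rotation about z by `theta`, translation `tr`)
rigid_move <- function(s, theta = pi / 3, tr = c(5, -2, 11)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(s$residues[c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, tr, FUN = "+")
  s$residues[c("x", "y", "z")] <- xyz
  s
}
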