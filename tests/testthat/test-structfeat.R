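test_that("superposing a structure onto itself is the identity", {
  s <- toy_complex()
  fit <- superpose(s, s)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition removes arbitrary rigid motions", {
  s <- toy_complex()
  moved <- rigid_move(s, theta = pi / 2, tr = c(10, 20, 30))
  expect_lt(superpose(moved, s)$rmsd, 1e-9)

  set.seed(5)
  for (k in 1:20) {
    cfg <- fixture_config(sigma = 0, deformation = 0, seed = k,
                          n_replicates = 1L)
    sr <- make_structure_replicates(cfg)
    expect_lt(superpose(sr$replicates[[1]], sr$reference)$rmsd, 1e-6)
  }
})

test_that("post-fit RMSD agrees with an independent least-squares oracle", {
  set.seed(21)
  # 4-point toy set with one point perturbed by 1 A
  P <- matrix(rnorm(12, sd = 4), 4, 3)
  Q <- P
  Q[2, 1] <- Q[2, 1] + 1
  mk <- function(m) complex_structure(data.frame(
    chain = "A", resno = 1:4, resname = "ALA", kind = "protein",
    x = m[, 1], y = m[, 2], z = m[, 3]))
  ours <- superpose(mk(P), mk(Q))$rmsd
  oracle <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(round(ours, 3), oracle)   # the oracle prints 3 decimals

  # larger random pair, same agreement
  A <- matrix(rnorm(60, sd = 6), 20, 3)
  B <- A + matrix(rnorm(60, sd = 0.7), 20, 3)
  mk2 <- function(m) complex_structure(data.frame(
    chain = "A", resno = seq_len(nrow(m)), resname = "ALA",
    kind = "protein", x = m[, 1], y = m[, 2], z = m[, 3]))
  expect_equal(round(superpose(mk2(A), mk2(B))$rmsd, 3),
               bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE))
})

test_that("superposition rejects underdetermined and degenerate input", {
  two <- complex_structure(data.frame(
    chain = "A", resno = 1:2, resname = "ALA", kind = "protein",
    x = c(0, 1), y = 0, z = 0))
  expect_error(superpose(two, two), "at least 3")
  line <- complex_structure(data.frame(
    chain = "A", resno = 1:5, resname = "ALA", kind = "protein",
    x = 1:5, y = 2 * (1:5), z = 3 * (1:5)))
  expect_error(superpose(line, line), "collinear|ill-conditioned")
})

test_that("residue displacements measure post-fit distances per residue", {
  s <- toy_complex()
  expect_true(all(residue_displacements(s, s)$displacement == 0))

  # one residue translated by 3 A in a fixed frame: displacement is exactly 3
  moved <- s
  moved$residues$x[4] <- moved$residues$x[4] + 3
  d <- residue_displacements(moved, s)
  expect_equal(d$displacement[d$residue == "A_4"], 3)
  expect_true(all(d$displacement[d$residue != "A_4"] == 0))
  expect_true(all(d$displacement >= 0))
})

test_that("RNA residues appear only when requested and present in reference", {
  full <- make_reference_complex(n_protein = 10, n_rna = 4)
  protein_only_ref <- complex_structure(
    full$residues[full$residues$kind == "protein", ])
  d1 <- residue_displacements(full, full, include_rna = TRUE)
  expect_identical(sum(d1$kind == "rna"), 4L)
  d2 <- residue_displacements(full, full, include_rna = FALSE)
  expect_identical(sum(d2$kind == "rna"), 0L)
  # model has RNA but the reference does not: only protein keys survive
  d3 <- residue_displacements(full, protein_only_ref, include_rna = TRUE)
  expect_identical(sort(d3$residue), sort(paste0("A_", 1:10)))
})

test_that("coordinate extraction flattens residues in order", {
  two <- complex_structure(data.frame(
    chain = "A", resno = 1:2, resname = "ALA", kind = "protein",
    x = c(1, 4), y = c(2, 5), z = c(3, 6)))
  v <- extract_coordinates(two)
  expect_identical(unname(v), c(1, 2, 3, 4, 5, 6))
  expect_identical(names(v)[1:3], c("A_1_x", "A_1_y", "A_1_z"))
  expect_identical(extract_coordinates(two), v)
  big <- make_reference_complex(n_protein = 871, n_rna = 8)
  expect_length(extract_coordinates(big), 2637L)
})

test_that("column rescaling maps min/max to 0/255 with half-up rounding", {
  expect_identical(as.integer(rescale_columns(matrix(c(0, 5, 10)))),
                   c(0L, 128L, 255L))
  expect_identical(as.integer(rescale_columns(matrix(c(7, 7, 7)))),
                   c(0L, 0L, 0L))
  expect_identical(as.integer(rescale_columns(matrix(c(-2, 13)))),
                   c(0L, 255L))
  # rank order within a column is preserved
  set.seed(8)
  v <- rnorm(50)
  r <- as.integer(rescale_columns(matrix(v)))
  expect_true(all(diff(r[order(v)]) >= 0))
  # a column already spanning 0..255 keeps its endpoints
  expect_identical(range(as.integer(rescale_columns(matrix(c(0, 100, 255))))),
                   c(0L, 255L))
  expect_error(rescale_columns(matrix(c(1, NA))), "non-finite")
})

test_that("sigma RSD matches hand computation and its invariances", {
  t1 <- data.frame(residue = c("A_1", "A_2"), kind = "protein",
                   displacement = c(1, 2))
  t2 <- data.frame(residue = c("A_1", "A_2"), kind = "protein",
                   displacement = c(3, 2))
  # residue A_1: sd([1,3]) / mean([1,3]) = sqrt(2)/2; residue A_2: 0
  expect_equal(sigma_rsd(list(t1, t2)), sqrt(2) / 2)

  # identical replicates score exactly zero
  expect_identical(sigma_rsd(list(t1, t1, t1)), 0)

  # scale invariance: multiplying all displacements by 10 changes nothing
  t1s <- t1; t1s$displacement <- t1s$displacement * 10
  t2s <- t2; t2s$displacement <- t2s$displacement * 10
  expect_equal(sigma_rsd(list(t1s, t2s)), sigma_rsd(list(t1, t2)))

  # zero-mean residues contribute zero rather than NaN
  z1 <- data.frame(residue = "A_1", kind = "protein", displacement = 0)
  expect_identical(sigma_rsd(list(z1, z1)), 0)

  expect_error(sigma_rsd(list(t1)), "at least 2")
  t3 <- data.frame(residue = c("A_1", "A_9"), kind = "protein",
                   displacement = c(1, 2))
  expect_error(sigma_rsd(list(t1, t3)), "key set")
})

test_that("sigma RSD ignores RNA residues", {
  t1 <- data.frame(residue = c("A_1", "B_1"), kind = c("protein", "rna"),
                   displacement = c(1, 100))
  t2 <- data.frame(residue = c("A_1", "B_1"), kind = c("protein", "rna"),
                   displacement = c(3, 1))
  expect_equal(sigma_rsd(list(t1, t2)), sqrt(2) / 2)
})

test_that("PDB round-trip preserves the residue-level structure", {
  s <- make_reference_complex(n_protein = 10, n_rna = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(s, path)
  back <- read_complex_pdb(path)
  expect_identical(nrow(back$residues), nrow(s$residues))
  expect_identical(back$residues$kind, s$residues$kind)
  expect_equal(back$residues$x, s$residues$x, tolerance = 1e-3)
})
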