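lib <- monomer_library()

test_that("circular fingerprints are deterministic and size-correct", {
  cfg <- fingerprint_config(256, 2)
  fp1 <- circular_fingerprint(lib$G, cfg)
  fp2 <- circular_fingerprint(lib$G, cfg)
  expect_identical(fp1, fp2)
  expect_length(fp1, 256L)
  expect_true(all(fp1 %in% 0:1))
  expect_gt(sum(fp1), 0)
})

test_that("a lone carbon atom sets exactly one bit", {
  # one atom has a single distinct environment at radius 1; popcount agrees
  # with an independent reference cheminformatics implementation on the
  # same molecule
  lone <- monomer_graph("C", matrix(numeric(0), ncol = 3))
  expect_identical(sum(circular_fingerprint(lone, fingerprint_config(32, 1))),
                   1L)
})

test_that("fingerprints are invariant under atom renumbering", {
  set.seed(7)
  cfg <- fingerprint_config(256, 2)
  for (g in lib[c("A", "G", "GNA_U", "AG_amide_dimer")]) {
    ref <- circular_fingerprint(g, cfg)
    for (k in 1:10) {
      perm <- sample(n_atoms(g))
      expect_identical(circular_fingerprint(permute_atoms(g, perm), cfg), ref)
    }
  }
})

test_that("distinct environment count is monotone in radius", {
  for (g in lib[c("A", "C", "G", "U", "GNA_U")]) {
    counts <- vapply(0:3, function(r) {
      length(siRNAfeat:::.environment_identifiers(g, r))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("bit packing is big-endian and shape-checked", {
  expect_identical(unclass(compress_bits(c(1, 0, 0, 0, 0, 0, 0, 1))), 129L)
  expect_identical(unclass(compress_bits(rep(0, 256))), rep(0L, 32))
  expect_length(compress_bits(rep(c(1, 0), 256)), 64L)   # 512 bits -> 64 bytes
  expect_error(compress_bits(rep(1, 12)), "divisible by 8")
  expect_error(compress_bits(c(1, 0, 2, 0, 0, 0, 0, 0)), "only 0 and 1")
})

test_that("packing and unpacking are mutually inverse for every byte", {
  for (b in 0:255) {
    bits <- unpack_bytes(b)
    expect_identical(unclass(compress_bits(bits)), b)
    expect_identical(pack_byte_naive(bits), as.numeric(b))
  }
  set.seed(3)
  bits <- sample(0:1, 512, replace = TRUE)
  expect_identical(unpack_bytes(compress_bits(bits)), as.integer(bits))
})

test_that("modification fingerprints give 64 + 32 compressed byte features", {
  v <- modification_fingerprints(lib$AG_dimer, lib$U)
  expect_length(v, 96L)
  expect_true(all(v >= 0 & v <= 255))
  # amide modification changes the dimer block
  vm <- modification_fingerprints(lib$AG_amide_dimer, lib$U)
  expect_false(identical(v[1:64], vm[1:64]))
  expect_identical(v[65:96], vm[65:96])   # same monomer part
  # GNA modification changes the monomer block
  vg <- modification_fingerprints(lib$AG_dimer, lib$GNA_U)
  expect_false(identical(v[65:96], vg[65:96]))
  expect_identical(modification_fingerprints(lib$AG_dimer, lib$U), v)
})

test_that("positional fingerprints encode 21 positions independently", {
  s1 <- strand_graphs(strrep("A", 21), list(), lib)
  v1 <- positional_fingerprints(s1)
  expect_length(v1, 672L)                 # 21 x 32
  expect_true(all(v1 %in% 0:1))

  # changing only position 7 (U -> GNA-U) changes only bit block 7
  useq <- strrep("U", 21)
  su <- strand_graphs(useq, list(), lib)
  sg <- strand_graphs(useq, list(modification_spec("GNA_MONOMER")), lib)
  vu <- positional_fingerprints(su)
  vg <- positional_fingerprints(sg)
  block7 <- 193:224                       # bits of position 7
  expect_false(identical(vu[block7], vg[block7]))
  expect_identical(vu[-block7], vg[-block7])

  expect_error(positional_fingerprints(s1[1:20]), "21")
})

test_that("progressive substitution rows respond only to element changes", {
  subs <- guanosine_substitutions()
  mat <- progressive_substitution(lib$guanosine_allC, subs)
  expect_identical(dim(mat), c(nrow(subs) + 1L, 32L))

  # carbon-for-carbon substitutions leave the fingerprint row unchanged
  carbon_steps <- which(subs$element == "C")
  for (k in carbon_steps) expect_identical(mat[k + 1L, ], mat[k, ])

  # heteroatom substitutions change the environment-identifier multiset
  # (checked unfolded: folding to 256 bits may occasionally collide), and
  # nearly all of them change the folded row too; the completed structure
  # matches an independent recomputation from the final molecule
  hetero_steps <- which(subs$element != "C")
  mol <- lib$guanosine_allC
  ids_prev <- sort(siRNAfeat:::.environment_identifiers(mol, 1L))
  for (j in seq_len(nrow(subs))) {
    mol <- substitute_elements(mol, subs$index[j], subs$element[j])
    ids <- sort(siRNAfeat:::.environment_identifiers(mol, 1L))
    if (subs$element[j] != "C") {
      expect_false(identical(ids, ids_prev), label = paste("step", j))
    } else {
      expect_identical(ids, ids_prev, label = paste("step", j))
    }
    ids_prev <- ids
  }
  changed <- vapply(hetero_steps, function(k) {
    !identical(mat[k + 1L, ], mat[k, ])
  }, logical(1))
  expect_gte(mean(changed), 0.9)
  expect_true(changed[1])                        # phosphorus insertion
  expect_true(changed[length(changed)])          # ring-completing nitrogen
  final_fp <- compress_bits(circular_fingerprint(lib$G,
                                                 fingerprint_config(256, 1)))
  expect_identical(unname(mat[nrow(mat), ]), unclass(final_fp))

  # zero substitutions: a single row equal to the skeleton fingerprint
  m0 <- progressive_substitution(lib$guanosine_allC,
                                 data.frame(index = integer(0),
                                            element = character(0)))
  expect_identical(dim(m0), c(1L, 32L))
  expect_identical(unname(m0[1L, ]), unname(mat[1L, ]))

  expect_error(progressive_substitution(
    lib$guanosine_allC, data.frame(index = 999, element = "N")),
    "out of range")
})

test_that("intermediate substitution rows match independently built molecules", {
  subs <- guanosine_substitutions()
  mat <- progressive_substitution(lib$guanosine_allC, subs)
  cfg <- fingerprint_config(256, 1)
  for (k in c(1L, 5L, nrow(subs))) {
    mol <- lib$guanosine_allC
    for (j in seq_len(k)) {
      mol <- substitute_elements(mol, subs$index[j], subs$element[j])
    }
    expect_identical(unname(mat[k + 1L, ]),
                     unclass(compress_bits(circular_fingerprint(mol, cfg))))
  }
})
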