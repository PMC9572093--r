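test_that("atom labels encode cyclicity and charge", {
  mols <- shared_mols()
  benzene <- mols$benzene
  expect_true(all(atom_labels(benzene)[benzene$element == "C"] == "C"))
  methanol <- mols$methanol
  expect_equal(atom_labels(methanol)[methanol$element == "O"], "-O")
  ma <- mols$methylammonium
  expect_equal(atom_labels(ma)[ma$element == "N"], "-N+")
})

test_that("MNA recursion matches hand-expanded examples", {
  mols <- shared_mols()
  d <- mna_descriptors(mols$methane, max_level = 1)
  expect_equal(d[["-C"]], 1L)
  expect_equal(d[["-H"]], 4L)
  expect_equal(d[["-C(-H-H-H-H)"]], 1L)
  expect_equal(d[["-H(-C)"]], 4L)
  expect_equal(sum(d), 10L)  # one descriptor per atom per level

  b <- mna_descriptors(mols$benzene, max_level = 1)
  expect_equal(b[["C(-HCC)"]], 6L)  # neighbor texts in lexicographic order
})

test_that("level-0 multiset size equals atom count for any molecule", {
  for (g in shared_mols()) {
    d <- mna_descriptors(g, max_level = 0)
    expect_equal(sum(d), n_atoms(g))
    # each level contributes exactly one descriptor per atom
    d3 <- mna_descriptors(g, max_level = 3)
    expect_equal(sum(d3), 4L * n_atoms(g))
  }
  expect_error(mna_descriptors(shared_mols()$methane, max_level = -1), ">= 0")
})

test_that("descriptor multisets are invariant under atom permutation", {
  g <- shared_mols()$phenol
  set.seed(7)
  ref <- mna_descriptors(g, 2)
  for (rep in 1:5) {
    perm <- sample(n_atoms(g))
    inv <- order(perm)
    g2 <- molecular_graph(g$element[perm],
                          cbind(inv[g$bonds[, 1]], inv[g$bonds[, 2]]),
                          g$charge[perm])
    d2 <- mna_descriptors(g2, 2)
    expect_identical(d2[sort(names(d2))], ref[sort(names(ref))])
  }
})

test_that("whole-molecule descriptors follow their additive definitions", {
  mols <- shared_mols()
  expect_equal(topological_length(mols$methane), 0L)
  expect_equal(topological_length(mols$butane), 3L)
  expect_equal(topological_length(mols$benzene), 3L)

  expect_equal(topological_volume(mols$methane, c(C = 1.0)), 1.0)
  expect_equal(topological_volume(mols$ethanol, c(C = 1.0, O = 0.8)), 2.8)
  expect_equal(topological_volume(mols$benzene, c(C = 0)), 0)
  expect_error(topological_volume(mols$ethanol, c(C = 1.0)), "O")

  expect_equal(lipophilicity(mols$ethanol, c(C = 0.5, O = -0.4, H = 0)), 0.6)
  expect_equal(lipophilicity(mols$benzene, c(C = 0, H = 0)), 0)
  # additivity: inserting CH2 under a positive-C scheme increases the value
  sch <- default_logp_table()
  expect_gt(lipophilicity(suppressWarnings(
    parse_structures("CCCCC pentane", "smiles"))[[1]], sch),
    lipophilicity(mols$butane, sch))
})

test_that("matrix assembly fixes column order and handles unseen descriptors", {
  mols <- shared_mols()
  v <- descriptor_vector(mols$methane, max_level = 1)
  M1 <- build_matrix(list(v))
  expect_equal(dim(M1), c(1L, length(v$counts) + 3L))
  expect_identical(tail(colnames(M1), 3),
                   c("topo_length", "topo_volume", "lipophilicity"))

  # identical compounds give identical rows; generation is deterministic
  M2 <- build_matrix(list(v, v))
  expect_identical(unname(M2[1, ]), unname(M2[2, ]))
  M1b <- build_matrix(list(descriptor_vector(mols$methane, max_level = 1)))
  expect_identical(M1, M1b)

  # prediction mode: unseen descriptors dropped and reported
  vb <- descriptor_vector(mols$benzene, max_level = 1)
  expect_message(Mp <- build_matrix(list(vb), vocabulary = names(v$counts)),
                 "absent")
  expect_true(attr(Mp, "unseen_fraction")[1] > 0)
  expect_error(build_matrix(list()), "empty")
})

test_that("training vocabulary order is first-seen then lexicographic", {
  mols <- shared_mols()
  vs <- lapply(mols[c("methane", "ethanol")], descriptor_vector, max_level = 1)
  M <- build_matrix(vs)
  vocab <- attr(M, "vocabulary")
  k1 <- sort(names(vs[[1]]$counts), method = "radix")
  expect_identical(vocab[seq_along(k1)], k1)
})
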