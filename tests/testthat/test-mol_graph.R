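test_that("vocabulary construction matches chemically forced contents", {
  v1 <- build_vocabulary("CCO")
  expect_equal(v1$atom_types, c("C", "O", "<PAD>", "<MASK>"))
  expect_equal(v1$charge_types, c("0", "<MASK>"))
  v2 <- build_vocabulary("CC(=O)[O-]")
  expect_equal(v2$charge_types, c("-1", "0", "<MASK>"))
  v3 <- build_vocabulary(c("CCO", "c1ccccc1N"))
  expect_equal(v3$atom_types, c("C", "N", "O", "<PAD>", "<MASK>"))
  expect_equal(v3$bond_types,
               c("none", "single", "double", "triple", "aromatic", "<MASK>"))
  # mask is last everywhere; no-bond is ordinary index 1
  expect_equal(mask_index(v3, "A"), length(v3$atom_types))
  expect_equal(v3$bond_types[1], "none")
  expect_error(build_vocabulary("not_a_molecule"), "unparsable")
})

test_that("smiles_to_graph encodes atoms, padding and symmetric bonds", {
  vocab <- test_vocab()
  g <- smiles_to_graph("CCO", vocab, 5)
  expect_equal(g$n_real, 3L)
  expect_true(check_graph(g, vocab, clean = TRUE))
  idx <- graph_indices(g)
  expect_equal(vocab$atom_types[idx$a], c("C", "C", "O", "<PAD>", "<PAD>"))
  # exactly two symmetric single-bond entry pairs
  single <- match("single", vocab$bond_types)
  expect_equal(sum(idx$e == single), 4L)
  expect_equal(idx$e[1, 2], single)
  expect_equal(idx$e[2, 3], single)
  # padding rows carry no bonds
  expect_true(all(idx$e[4:5, ] == 1L))

  tri <- smiles_to_graph("C1CC1", vocab, 3)
  expect_equal(tri$n_real, 3L)
  itri <- graph_indices(tri)
  expect_equal(sum(itri$e == single), 6L)  # 3 bonds, mirrored

  co2 <- smiles_to_graph("O=C=O", vocab, 4)
  ico2 <- graph_indices(co2)
  dbl <- match("double", vocab$bond_types)
  expect_equal(sum(ico2$e == dbl), 4L)
  expect_true(all(ico2$c[1:3] == neutral_charge_index(vocab)))

  expect_error(smiles_to_graph("CCCCCC", vocab, 4), "larger than graph size")
  expect_error(smiles_to_graph("CCS", vocab, 6), "not in vocabulary")
})

test_that("graph_to_smiles inverts encoding and keeps the largest component", {
  vocab <- test_vocab()
  expect_equal(graph_to_smiles(smiles_to_graph("C1CC1", vocab, 5), vocab),
               "C1CC1")
  # two components: C-C-O (3 atoms) and C-C (2 atoms) -> largest wins
  single <- match("single", vocab$bond_types)
  C <- match("C", vocab$atom_types); O <- match("O", vocab$atom_types)
  e <- matrix(1L, 5, 5)
  e[1, 2] <- e[2, 1] <- single; e[2, 3] <- e[3, 2] <- single
  e[4, 5] <- e[5, 4] <- single
  g <- graph_from_indices(c(C, C, O, C, C),
                          rep(neutral_charge_index(vocab), 5), e, vocab)
  expect_equal(graph_to_smiles(g, vocab), "CCO")
  # pentavalent carbon fails sanitization -> failure flag, not an error
  e2 <- matrix(1L, 6, 6)
  e2[1, 2:6] <- e2[2:6, 1] <- single
  bad <- graph_from_indices(rep(C, 6), rep(neutral_charge_index(vocab), 6),
                            e2, vocab)
  expect_true(is.na(graph_to_smiles(bad, vocab)))
  # masked graphs are a contract violation, not an invalid molecule
  gm <- corrupt_graph(smiles_to_graph("CCO", vocab, 5), 10,
                      test_schedule(10))
  expect_error(graph_to_smiles(gm, vocab), "MASK")
})

test_that("round trip holds for every fixture molecule", {
  vocab <- build_vocabulary(c("CCO", "CC(=O)[O-]", "c1ccccc1N", "C#N",
                              "O=C=O", "C1CC1"))
  for (s in c("CCO", "CC(=O)[O-]", "c1ccccc1N", "C#N", "O=C=O", "C1CC1")) {
    canon <- canonical_smiles(s)
    g <- smiles_to_graph(s, vocab, 9)
    expect_equal(graph_to_smiles(g, vocab), canon)
  }
})

test_that("permute_graph is consistent and decoding is permutation-invariant", {
  vocab <- test_vocab()
  g <- smiles_to_graph("CCO", vocab, 5)
  expect_equal(permute_graph(g, 1:5), g)
  expect_error(permute_graph(g, c(1, 1, 2, 3, 4)), "permutation")
  # inverse composition restores the graph
  set.seed(1)
  for (rep in 1:5) {
    perm <- sample(5)
    inv <- order(perm)
    expect_equal(permute_graph(permute_graph(g, perm), inv), g)
  }
  # exhaustive on n = 4: decoded SMILES invariant under all permutations
  g4 <- smiles_to_graph("CCO", vocab, 4)
  canon <- graph_to_smiles(g4, vocab)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  decoded <- graphs_to_smiles(
    lapply(seq_len(nrow(perms)),
           function(r) permute_graph(g4, as.integer(perms[r, ]))), vocab)
  expect_true(all(decoded == canon))
})
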