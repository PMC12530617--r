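# Builds denoiser-output shaped objects directly so the loss terms can be
# checked against closed forms and enumeration oracles without a network.

point_mass_output <- function(g0, vocab) {
  idx <- graph_indices(g0)
  n <- g0$n
  ap <- onehot_matrix(idx$a, vocab$K_A)
  cp <- onehot_matrix(idx$c, vocab$K_C)
  ep <- array(0, dim = c(n, n, vocab$K_E))
  for (i in seq_len(n)) for (j in seq_len(n)) ep[i, j, idx$e[i, j]] <- 1
  structure(list(atom_probs = ap, charge_probs = cp, edge_probs = ep),
            class = "denoiser_output")
}

random_output <- function(n, vocab) {
  rnd <- function(m, k) {
    x <- matrix(stats::rexp(m * k), m, k)
    x / rowSums(x)
  }
  ep_flat <- rnd(n * n, vocab$K_E)
  # symmetrize like the network: average mirrored entries
  ep <- array(ep_flat, dim = c(n, n, vocab$K_E))
  ep <- (ep + aperm(ep, c(2, 1, 3))) / 2
  structure(list(atom_probs = rnd(n, vocab$K_A),
                 charge_probs = rnd(n, vocab$K_C), edge_probs = ep),
            class = "denoiser_output")
}

test_that("oracle point-mass predictions zero out the VLB and CE", {
  vocab <- test_vocab()
  sch <- test_schedule(8)
  g0 <- smiles_to_graph("CC(=O)[O-]", vocab, 6)
  out <- point_mass_output(g0, vocab)
  set.seed(2)
  for (t in 2:8) {
    gt <- corrupt_graph(g0, t, sch)
    v <- vlb_terms(g0, gt, t, out, sch)
    expect_true(all(abs(v) <= 1e-8))
  }
  # default schedule: the prior term is exactly zero at t = T
  gt <- corrupt_graph(g0, 8, sch)
  expect_equal(unname(attr(vlb_terms(g0, gt, 8, out, sch), "prior")),
               c(0, 0, 0))
  expect_equal(unname(ce_terms(g0, out)), c(0, 0, 0))
  expect_error(vlb_terms(g0, g0, 0, out, sch), "t must be")
})

test_that("uniform predictions give CE = log K exactly", {
  vocab <- test_vocab()
  g0 <- smiles_to_graph("CCO", vocab, 5)
  n <- 5
  out <- structure(list(
    atom_probs = matrix(1 / vocab$K_A, n, vocab$K_A),
    charge_probs = matrix(1 / vocab$K_C, n, vocab$K_C),
    edge_probs = array(1 / vocab$K_E, dim = c(n, n, vocab$K_E))),
    class = "denoiser_output")
  ce <- ce_terms(g0, out)
  expect_equal(unname(ce),
               log(c(vocab$K_A, vocab$K_C, vocab$K_E)), tolerance = 1e-12)
})

test_that("VLB matches a term-by-term enumeration oracle", {
  vocab <- test_vocab()
  sch <- test_schedule(4)
  g0 <- smiles_to_graph("CCO", vocab, 4)
  idx0 <- graph_indices(g0)
  set.seed(9)
  for (t in 2:4) {
    gt <- corrupt_graph(g0, t, sch)
    idxt <- graph_indices(gt)
    out <- random_output(4, vocab)
    got <- vlb_terms(g0, gt, t, out, sch)
    # oracle: loop every entry, enumerate x_{t-1}, sum KL terms
    kl_entry <- function(x0, xt, probs, channel) {
      q <- oracle_posterior(xt, x0, t, channel, sch)
      K <- length(probs)
      p <- numeric(K + 1)
      for (x0h in seq_len(K)) {
        p <- p + probs[x0h] * oracle_posterior(xt, x0h, t, channel, sch)
      }
      sum(ifelse(q > 0, q * (log(q) - log(pmax(p, 1e-30))), 0))
    }
    want_A <- sum(vapply(1:4, function(i) {
      kl_entry(idx0$a[i], idxt$a[i], out$atom_probs[i, ], "A")
    }, numeric(1)))
    want_E <- 0
    for (i in 2:4) for (j in seq_len(i - 1)) {
      want_E <- want_E + kl_entry(idx0$e[i, j], idxt$e[i, j],
                                  out$edge_probs[i, j, ], "E")
    }
    expect_lt(abs(got[["A"]] - want_A), 1e-10)
    expect_lt(abs(got[["E"]] - want_E), 1e-10)
  }
})

test_that("CE matches a direct summation oracle on random predictions", {
  vocab <- test_vocab()
  g0 <- smiles_to_graph("CC(=O)[O-]", vocab, 5)
  idx0 <- graph_indices(g0)
  set.seed(10)
  out <- random_output(5, vocab)
  got <- ce_terms(g0, out)
  want_A <- -mean(log(out$atom_probs[cbind(1:5, idx0$a)]))
  ev <- c(); tv <- c()
  for (i in 2:5) for (j in seq_len(i - 1)) {
    ev <- c(ev, -log(out$edge_probs[i, j, idx0$e[i, j]]))
  }
  expect_equal(got[["A"]], want_A, tolerance = 1e-12)
  expect_equal(got[["E"]], mean(ev), tolerance = 1e-12)
})

test_that("total_loss is the weighted sum and rejects non-finite terms", {
  v <- c(A = 1, C = 1, E = 1); ce <- c(A = 1, C = 1, E = 1)
  expect_equal(total_loss(v, ce, c(1, 1, 5, 0.5, 0.5, 2.5)), 10.5)
  expect_equal(total_loss(v * 0, ce * 0), 0)
  expect_equal(total_loss(c(A = 7, C = 0, E = 0), ce * 0,
                          c(1, 0, 0, 0, 0, 0)), 7)
  expect_error(total_loss(c(A = NaN, C = 1, E = 1), ce), "vlb_A")
})

test_that("KL pieces are non-negative and loss is permutation-invariant", {
  vocab <- test_vocab()
  sch <- test_schedule(6)
  g0 <- smiles_to_graph("CC(=O)[O-]", vocab, 5)
  set.seed(12)
  for (t in c(2, 4, 6)) {
    gt <- corrupt_graph(g0, t, sch)
    out <- random_output(5, vocab)
    v <- vlb_terms(g0, gt, t, out, sch)
    expect_true(all(v >= -1e-12))
    # permute everything together: each term unchanged
    perm <- sample(5)
    gp0 <- permute_graph(g0, perm)
    gpt <- permute_graph(gt, perm)
    outp <- structure(list(atom_probs = out$atom_probs[perm, , drop = FALSE],
                           charge_probs = out$charge_probs[perm, , drop = FALSE],
                           edge_probs = out$edge_probs[perm, perm, , drop = FALSE]),
                      class = "denoiser_output")
    expect_equal(unname(vlb_terms(gp0, gpt, t, outp, sch)), unname(v),
                 tolerance = 1e-8)
    expect_equal(unname(ce_terms(gp0, outp)), unname(ce_terms(g0, out)),
                 tolerance = 1e-8)
  }
})
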