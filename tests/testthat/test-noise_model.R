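test_that("schedule construction satisfies its mass constraints", {
  # single-step full mask
  s1 <- make_schedule(1, c(A = 3), mask_fraction_final = 1,
                      uniform_weight = 0)
  expect_equal(s1$channels$A$gamma, 1)
  expect_equal(s1$channels$A$alpha, 0)
  expect_equal(s1$channels$A$beta, 0)
  # default schedule: terminal cumulative mask mass 1 - prod(1 - gamma_t)
  # equals 1
  s10 <- test_schedule(10)
  for (ch in names(s10$channels)) {
    expect_lt(abs((1 - prod(1 - s10$channels[[ch]]$gamma)) - 1), 1e-9)
    expect_lt(abs(s10$channels[[ch]]$gbar[10] - 1), 1e-9)
  }
  # per-step constraint alpha + K beta + gamma = 1 for every channel/t
  set.seed(4)
  for (rep in 1:10) {
    K <- sample(2:6, 1)
    s <- random_schedule(K, sample(1:8, 1))
    ch <- s$channels$A
    expect_equal(ch$alpha + K * ch$beta + ch$gamma, rep(1, s$T),
                 tolerance = 1e-12)
  }
  expect_error(make_schedule(5, c(A = 3), kind = "nope"), "unknown schedule")
})

test_that("transition matrices have the mask-and-replace structure", {
  # alpha = 1 limit is the identity; gamma = 1 limit maps all to mask
  expect_equal(mask_replace_matrix(3, 1, 0, 0), diag(4))
  Qm <- mask_replace_matrix(3, 0, 0, 1)
  expect_true(all(Qm[4, ] == 1))
  # direct entry evaluation, K = 2
  Q <- mask_replace_matrix(2, 0.8, 0.05, 0.1)
  expect_equal(Q[, 1], c(0.85, 0.05, 0.1))
  expect_equal(colSums(Q), rep(1, 3))
  # mask column absorbing exactly
  sch <- test_schedule(10)
  for (t in c(1, 5, 10)) {
    Q <- transition_matrix(t, "E", sch)
    expect_identical(Q[, ncol(Q)],
                     c(rep(0, ncol(Q) - 1), 1))
  }
  expect_error(transition_matrix(11, "A", sch), "out of range")
})

test_that("closed-form cumulative matrices match explicit products", {
  sch <- test_schedule(10)
  expect_equal(cumulative_matrix(0, "A", sch),
               diag(schedule_channel(sch, "A")$K + 1))
  # terminal: every ordinary column is fully masked
  QT <- cumulative_matrix(10, "A", sch)
  expect_true(all(abs(QT[nrow(QT), -ncol(QT)] - 1) < 1e-9))
  set.seed(11)
  for (rep in 1:10) {
    K <- sample(2:6, 1)
    Tt <- sample(2:8, 1)
    s <- random_schedule(K, Tt)
    t <- sample(Tt, 1)
    P <- diag(K + 1)
    for (u in seq_len(t)) P <- transition_matrix(u, "A", s) %*% P
    expect_lt(max(abs(P - cumulative_matrix(t, "A", s))), 1e-10)
    expect_equal(colSums(cumulative_matrix(t, "A", s)), rep(1, K + 1),
                 tolerance = 1e-12)
  }
})

test_that("posterior matches brute-force Bayes enumeration", {
  set.seed(21)
  for (rep in 1:6) {
    K <- sample(2:6, 1)
    Tt <- sample(2:8, 1)
    s <- random_schedule(K, Tt)
    for (t in seq_len(Tt)) {
      for (x_t in seq_len(K + 1)) {
        for (x0 in seq_len(K)) {
          p <- posterior(x_t, x0, t, "A", s)
          o <- oracle_posterior(x_t, x0, t, "A", s)
          if (isTRUE(attr(p, "unreachable"))) {
            expect_equal(sum(o), 0)
          } else {
            expect_lt(max(abs(p - o)), 1e-10)
            expect_lt(abs(sum(p) - 1), 1e-12)
          }
        }
      }
    }
  }
  sch <- test_schedule(5)
  # t = 1: any reachable x_1 gives a point mass on x0
  p <- posterior(1, 1, 1, "A", sch)
  expect_equal(which.max(p), 1L)
  expect_equal(sum(p), 1)
  expect_equal(max(p), 1)
  expect_error(posterior(1, mask_index(test_vocab(), "A"), 2, "A", sch),
               "ordinary")
})

test_that("corruption is identity at t = 0 and fully masked at t = T", {
  vocab <- test_vocab()
  sch <- test_schedule(10)
  g0 <- smiles_to_graph("CCO", vocab, 5)
  expect_identical(corrupt_graph(g0, 0, sch), g0)
  gT <- corrupt_graph(g0, 10, sch)
  idx <- graph_indices(gT)
  expect_true(all(idx$a == mask_index(vocab, "A")))
  expect_true(all(idx$c == mask_index(vocab, "C")))
  off <- row(idx$e) != col(idx$e)
  expect_true(all(idx$e[off] == mask_index(vocab, "E")))
  # diagonal untouched, symmetry preserved
  expect_true(all(diag(idx$e) == 1L))
  expect_true(all(idx$e == t(idx$e)))
  expect_error(corrupt_graph(gT, 5, sch), "clean graph")
})

test_that("empirical corruption frequencies match the cumulative column", {
  vocab <- build_vocabulary("CO")  # 1 real atom in a 1-node graph: C or O
  sch <- test_schedule(10, vocab)
  g0 <- smiles_to_graph("C", vocab, 1)
  t <- 5
  nrep <- 20000
  set.seed(33)
  draws <- vapply(seq_len(nrep), function(i) {
    graph_indices(corrupt_graph(g0, t, sch))$a
  }, integer(1))
  col <- cumulative_matrix(t, "A", sch)[, graph_indices(g0)$a]
  emp <- tabulate(draws, nbins = length(col)) / nrep
  se <- sqrt(col * (1 - col) / nrep)
  expect_true(all(abs(emp - col) <= 4 * pmax(se, 1e-12) + 1e-9))
})

test_that("mask state is absorbing along stepwise trajectories", {
  set.seed(55)
  K <- 4
  s <- random_schedule(K, 8)
  x <- rep(1L, 2000)
  masked_at <- rep(NA_integer_, 2000)
  for (t in 1:8) {
    Q <- transition_matrix(t, "A", s)
    x <- sample_from_columns(Q, x)
    newly <- is.na(masked_at) & x == K + 1
    masked_at[newly] <- t
    # anything masked before stays masked
    expect_true(all(x[!is.na(masked_at) & masked_at < t] == K + 1))
  }
})

test_that("stepwise and jump corruption give indistinguishable marginals", {
  set.seed(77)
  K <- 4
  s <- random_schedule(K, 6)
  n <- 100000
  xstep <- rep(2L, n)
  for (t in 1:4) {
    xstep <- sample_from_columns(transition_matrix(t, "A", s), xstep)
  }
  xjump <- sample_from_columns(cumulative_matrix(4, "A", s), rep(2L, n))
  tab <- rbind(tabulate(xstep, K + 1), tabulate(xjump, K + 1))
  keep <- colSums(tab) > 0
  expect_gt(suppressWarnings(stats::chisq.test(tab[, keep]))$p.value, 0.01)
})
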