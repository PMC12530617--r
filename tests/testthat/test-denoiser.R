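test_that("denoiser output satisfies its distribution invariants", {
  vocab <- test_vocab()
  sch <- test_schedule(10)
  model <- tiny_model(vocab, sch, n = 5)
  g0 <- smiles_to_graph("CC(=O)[O-]", vocab, 5)
  set.seed(2)
  for (t in c(1, 5, 10)) {
    gt <- corrupt_graph(g0, t, sch)
    out <- predict_clean(model, gt, t)
    expect_lt(max(abs(rowSums(out$atom_probs) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(out$charge_probs) - 1)), 1e-6)
    expect_lt(max(abs(apply(out$edge_probs, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(out$atom_probs >= 0), all(out$edge_probs >= 0))
    # no mass on <MASK>: output widths are the ordinary counts
    expect_equal(ncol(out$atom_probs), vocab$K_A)
    expect_equal(dim(out$edge_probs)[3], vocab$K_E)
    # exact edge symmetry
    expect_identical(out$edge_probs, aperm(out$edge_probs, c(2, 1, 3)))
  }
  expect_error(predict_clean(model, g0, 11), "out of range")
})

test_that("conditional models require a condition value", {
  vocab <- test_vocab()
  sch <- test_schedule(6)
  model <- tiny_model(vocab, sch, n = 4, condition_dim = 4)
  model$cond_stats <- list(mean = 0, sd = 1)
  g <- smiles_to_graph("CCO", vocab, 4)
  expect_error(predict_clean(model, g, 3), "condition")
  out <- predict_clean(model, g, 3, condition = 1.5)
  expect_lt(max(abs(rowSums(out$atom_probs) - 1)), 1e-6)
})

test_that("denoiser is permutation-equivariant when RNI permutes too", {
  vocab <- test_vocab()
  sch <- test_schedule(6)
  model <- tiny_model(vocab, sch, n = 4, seed = 7)
  g0 <- smiles_to_graph("CCO", vocab, 4)
  set.seed(3)
  gt <- corrupt_graph(g0, 3, sch)
  rni <- matrix(stats::rnorm(4 * model$config$rni_dim), 4)
  base <- predict_clean(model, gt, 3, rni_noise = rni)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  for (r in seq_len(nrow(perms))) {
    perm <- as.integer(perms[r, ])
    outp <- predict_clean(model, permute_graph(gt, perm), 3,
                          rni_noise = rni[perm, , drop = FALSE])
    expect_lt(max(abs(outp$atom_probs - base$atom_probs[perm, ])), 1e-5)
    expect_lt(max(abs(outp$charge_probs - base$charge_probs[perm, ])), 1e-5)
    expect_lt(max(abs(outp$edge_probs - base$edge_probs[perm, perm, ])),
              1e-5)
  }
})

test_that("autodiff gradients agree with numerical differentiation", {
  vocab <- test_vocab()
  sch <- test_schedule(6)
  conf <- denoiser_config(layers = 2, hidden = 8, heads = 2, dropout = 0,
                          rni_dim = 3, time_embed_dim = 4,
                          condition_dim = 4)
  set.seed(42)
  params <- init_denoiser(conf, vocab)
  n <- 4
  idx0 <- lapply(c("CCO", "CO"),
                 function(s) graph_indices(smiles_to_graph(s, vocab, n)))
  t_vec <- c(3L, 1L)
  cond <- c(0.5, -1.2)
  idxt <- lapply(1:2, function(b) {
    corrupt_indices(idx0[[b]]$a, idx0[[b]]$c, idx0[[b]]$e, t_vec[b], sch)
  })
  w <- default_loss_weights()
  rni <- matrix(stats::rnorm(2 * n * conf$rni_dim), 2 * n, conf$rni_dim)
  loss_fn <- function(p, use_tape = FALSE) {
    if (use_tape) {
      ad_tape_start()
      p <- lapply(p, ad_param)
    }
    batch <- make_batch(idxt, vocab)
    fw <- denoiser_forward(p, conf, vocab, batch, t_vec, sch$T, cond = cond,
                           rni = rni)
    bl <- batch_loss(fw, idx0, idxt, t_vec, sch, w, vocab)
    if (use_tape) {
      ad_backward(bl$loss)
      g <- lapply(p, function(x) x$grad)
      ad_tape_stop()
      return(list(loss = as.numeric(ad_value(bl$loss)), grads = g))
    }
    as.numeric(ad_value(bl$loss))
  }
  res <- loss_fn(params, use_tape = TRUE)
  eps <- 1e-6
  set.seed(7)
  for (nm in sample(names(params), 20)) {
    idx <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] + eps
    p3 <- params; p3[[nm]][idx] <- p3[[nm]][idx] - eps
    num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
    ana <- if (is.null(res$grads[[nm]])) 0 else res$grads[[nm]][idx]
    expect_lt(abs(num - ana) / max(1e-6, abs(num), abs(ana)), 1e-4)
  }
})

test_that("an untrained model still yields decodable samples end to end", {
  vocab <- test_vocab()
  sch <- test_schedule(8)
  model <- tiny_model(vocab, sch, n = 5, seed = 9)
  set.seed(1)
  s <- sample_molecules(model, 5, seed = 4)
  expect_length(s$smiles, 5)
  expect_length(s$graphs, 5)
  for (g in s$graphs) expect_true(check_graph(g, vocab, clean = TRUE))
})

test_that("a small instance can fit a single molecule (capacity smoke test)", {
  # a zero-headroom graph makes every denoising conditional deterministic
  # (no exchangeable-row entropy floor), so a few hundred steps must cut
  # the training loss to well below a tenth of its starting value
  cfg <- desk_train_config(T_steps = 10, epochs = 150, batch_size = 8,
                           n_headroom = 0, seed = 2)
  m <- train_model(rep("CC", 8), cfg)
  last <- nrow(m$log)
  expect_lt(m$log$train_loss[last], 0.1 * m$log$train_loss[1])
  ce0 <- sum(m$log[1, c("ce_A", "ce_C", "ce_E")])
  ceN <- sum(m$log[last, c("ce_A", "ce_C", "ce_E")])
  expect_lt(ceN, 0.1 * ce0)
})
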