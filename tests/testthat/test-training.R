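test_that("split_dataset apportions sizes and reproduces with a seed", {
  mols <- sprintf("C%s", strrep("C", 0:9))
  sp <- split_dataset(mols, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(sp), c(train = 8L, valid = 1L, test = 1L))
  expect_setequal(c(sp$train, sp$valid, sp$test), mols)
  sp2 <- split_dataset(mols, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_dataset(mols, c(1, 0, 0)), "positive")
  expect_error(split_dataset(mols[1:2]), "at least 3")
})

test_that("training is seed-deterministic and logs loss components", {
  cfg <- desk_train_config(T_steps = 6, epochs = 3, batch_size = 4, seed = 11)
  cfg$denoiser <- denoiser_config(layers = 1, hidden = 16, heads = 2,
                                  dropout = 0, rni_dim = 4,
                                  time_embed_dim = 8)
  m1 <- train_model(c("CCO", "CCC", "CO", "CC"), cfg)
  m2 <- train_model(c("CCO", "CCC", "CO", "CC"), cfg)
  expect_equal(m1$log$train_loss, m2$log$train_loss, tolerance = 1e-6)
  expect_true(all(c("epoch", "train_loss", "valid_loss", "vlb_A", "vlb_C",
                    "vlb_E", "ce_A", "ce_C", "ce_E") %in% names(m1$log)))
  # dataset order must not matter under the same seed-derived shuffling
  m3 <- train_model(c("CC", "CO", "CCC", "CCO"), cfg)
  expect_equal(sort(m1$train_canonical), sort(m3$train_canonical))
})

test_that("an untrained (0-epoch) checkpoint is usable by the sampler", {
  cfg <- desk_train_config(T_steps = 5, epochs = 0, batch_size = 4, seed = 2)
  cfg$denoiser <- denoiser_config(layers = 1, hidden = 16, heads = 2,
                                  dropout = 0, rni_dim = 4,
                                  time_embed_dim = 8)
  m <- train_model(c("CCO", "CCC", "CO"), cfg)
  expect_equal(nrow(m$log), 0)
  s <- sample_molecules(m, 3, seed = 1)
  expect_length(s$smiles, 3)
})

test_that("the selected checkpoint is at least as good as the final one", {
  cfg <- desk_train_config(T_steps = 6, epochs = 8, batch_size = 8, seed = 3)
  cfg$denoiser <- denoiser_config(layers = 1, hidden = 16, heads = 2,
                                  dropout = 0, rni_dim = 4,
                                  time_embed_dim = 8)
  m <- train_model(rep(c("CCO", "CC"), 4), cfg)
  expect_lte(m$best_valid_loss, m$log$valid_loss[nrow(m$log)])
})

test_that("checkpoints and run configs round-trip through files", {
  cfg <- desk_train_config(T_steps = 5, epochs = 0, seed = 6)
  m <- train_model(c("CCO", "CC", "CO"), cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$vocab, m2$vocab)
  s1 <- sample_molecules(m, 3, seed = 5)
  s2 <- sample_molecules(m2, 3, seed = 5)
  expect_identical(s1$smiles, s2$smiles)
  ypath <- tempfile(fileext = ".yaml")
  write_run_config(cfg, ypath)
  cfg2 <- read_run_config(ypath)
  expect_equal(cfg2$T_steps, cfg$T_steps)
  expect_equal(cfg2$denoiser$hidden, cfg$denoiser$hidden)
  expect_equal(unname(cfg2$loss_weights), unname(cfg$loss_weights))
})

test_that("conditioning requires a matching property column", {
  cfg <- desk_train_config(T_steps = 5, epochs = 0, seed = 1,
                           condition_on = "logp")
  expect_error(train_model(c("CCO", "CC", "CO"), cfg), "property column")
  props <- data.frame(logp = c(0.1, 0.8, -0.3))
  m <- train_model(c("CCO", "CC", "CO"), cfg, properties = props)
  expect_gt(m$config$condition_dim, 0)
  expect_equal(m$cond_stats$mean, mean(props$logp))
  s <- sample_molecules(m, 2, condition = 0.5, seed = 3)
  expect_length(s$smiles, 2)
  expect_error(sample_molecules(m, 2, seed = 3), "condition")
})
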