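# Training loop: uniform timestep draws, forward corruption, batched
# denoiser forward, weighted VLB + CE loss, AdamW with global gradient-norm
# clipping, best-validation-loss checkpoint selection.

#' Training configuration
#'
#' Defaults follow the reference setup (AdamW, learning rate 1e-4, weight
#' decay 1e-4, batch size 128, 500 epochs, gradient norm clipped to 1,
#' diffusion length T = 500); [desk_train_config()] provides a small-scale
#' preset for CPU-sized corpora.
#'
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param batch_size molecules per optimization step.
#' @param epochs passes over the training set (0 returns an initialized,
#'   sampleable checkpoint).
#' @param grad_clip_norm global gradient-norm clip (> 0).
#' @param seed root seed governing initialization, timestep draws,
#'   corruption, RNI and dropout.
#' @param T_steps diffusion steps of the noise schedule.
#' @param schedule_kind,mask_fraction_final,uniform_weight passed to
#'   [make_schedule()].
#' @param loss_weights see [default_loss_weights()].
#' @param denoiser a [denoiser_config()].
#' @param n_headroom padding rows added beyond the training maximum
#'   heavy-atom count (free rows for optimization).
#' @param condition_on name of the property column to condition on, or NULL.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, batch_size = 128,
                         epochs = 500, grad_clip_norm = 1, seed = 0,
                         T_steps = 500, schedule_kind = "linear-mask",
                         mask_fraction_final = 1, uniform_weight = 0.05,
                         loss_weights = default_loss_weights(),
                         denoiser = denoiser_config(),
                         n_headroom = 2, condition_on = NULL,
                         adam_beta2 = 0.999) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0,
            grad_clip_norm > 0, T_steps >= 1, n_headroom >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), grad_clip_norm = grad_clip_norm,
                 seed = as.integer(seed), T_steps = as.integer(T_steps),
                 schedule_kind = schedule_kind,
                 mask_fraction_final = mask_fraction_final,
                 uniform_weight = uniform_weight,
                 loss_weights = loss_weights, denoiser = denoiser,
                 n_headroom = as.integer(n_headroom),
                 condition_on = condition_on,
                 adam_beta2 = adam_beta2),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' Small model and short diffusion for enumerated fixture corpora on one
#' CPU: 2 layers, width 64, 4 heads, no dropout, T = 24, batch 32, a larger
#' learning rate and a faster-adapting second Adam moment suited to runs of
#' a few hundred steps.
#'
#' @param ... overrides forwarded to [train_config()].
#' @export
desk_train_config <- function(...) {
  defaults <- list(lr = 4e-3, weight_decay = 1e-4, batch_size = 32,
                   epochs = 300, T_steps = 24, adam_beta2 = 0.99,
                   denoiser = denoiser_config(layers = 2, hidden = 64,
                                              heads = 4, dropout = 0,
                                              rni_dim = 8,
                                              time_embed_dim = 16))
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Random train/validation/test split
#'
#' @param smiles_list character vector (length >= 3).
#' @param ratios positive fractions summing to 1 (default 8:1:1).
#' @param seed optional seed for the permutation.
#' @return list `train`, `valid`, `test`; sizes are within 1 of the exact
#'   fractions (largest-remainder apportionment).
#' @export
split_dataset <- function(smiles_list, ratios = c(0.8, 0.1, 0.1),
                          seed = NULL) {
  n <- length(smiles_list)
  if (n < 3) stop("need at least 3 molecules to split")
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive fractions")
  }
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  exact <- n * ratios
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  stops <- cumsum(sizes)
  list(train = smiles_list[perm[seq_len(stops[1])]],
       valid = smiles_list[perm[(stops[1] + 1):stops[2]]],
       test = smiles_list[perm[(stops[2] + 1):stops[3]]])
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), step = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) {
    if (is.null(g)) 0 else sum(g^2)
  }, numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) if (is.null(g)) g else g * (max_norm / total))
  }
  grads
}

# timesteps are drawn stratified across the batch (marginally uniform on
# 1..T, one draw per stratum, order shuffled) to cut gradient variance
stratified_timesteps <- function(T_steps, B) {
  u <- stats::runif(B)
  t_vec <- ceiling(T_steps * (seq_len(B) - u) / B)
  sample(pmin(pmax(t_vec, 1L), T_steps))
}

# linear warmup over the first tenth of the step budget, then cosine decay
# to 10% of the peak learning rate
lr_at <- function(lr, step, total) {
  warm <- max(1, round(0.1 * total))
  if (step <= warm) return(lr * step / warm)
  frac <- (step - warm) / max(1, total - warm)
  lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
}

# one optimization step over a batch of clean index graphs; returns params,
# optimizer state and the loss components
training_step <- function(params, opt, config, vocab, schedule, batch_idx0,
                          cond_vals, lr) {
  B <- length(batch_idx0)
  t_vec <- stratified_timesteps(schedule$T, B)
  idxt <- lapply(seq_len(B), function(b) {
    g <- batch_idx0[[b]]
    corrupt_indices(g$a, g$c, g$e, t_vec[b], schedule)
  })
  ad_tape_start()
  pnodes <- lapply(params, ad_param)
  batch <- make_batch(idxt, vocab)
  fw <- denoiser_forward(pnodes, config$denoiser, vocab, batch, t_vec,
                         schedule$T, cond = cond_vals, training = TRUE)
  bl <- batch_loss(fw, batch_idx0, idxt, t_vec, schedule,
                   config$loss_weights, vocab)
  loss_val <- as.numeric(ad_value(bl$loss))
  if (!is.finite(loss_val)) {
    ad_tape_stop()
    stop("non-finite training loss (components: ",
         paste(sprintf("%s=%.4g", names(bl$components), bl$components),
               collapse = ", "), ")")
  }
  ad_backward(bl$loss)
  grads <- lapply(pnodes, function(p) p$grad)
  ad_tape_stop()
  grads <- clip_gradients(grads, config$grad_clip_norm)
  upd <- adamw_step(params, grads, opt, lr, config$weight_decay,
                    beta2 = config$adam_beta2 %||% 0.999)
  list(params = upd$params, opt = upd$state, loss = loss_val,
       components = bl$components)
}

# Monte-Carlo validation loss with a fixed RNG substream so values are
# comparable across epochs; restores the global RNG state afterwards.
validation_loss <- function(params, config, vocab, schedule, idx_list,
                            cond_vals, eval_seed) {
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(eval_seed)
  total <- 0
  chunks <- split(seq_along(idx_list),
                  ceiling(seq_along(idx_list) / config$batch_size))
  for (ch in chunks) {
    B <- length(ch)
    t_vec <- sample.int(schedule$T, B, replace = TRUE)
    idxt <- lapply(seq_len(B), function(b) {
      g <- idx_list[[ch[b]]]
      corrupt_indices(g$a, g$c, g$e, t_vec[b], schedule)
    })
    batch <- make_batch(idxt, vocab)
    fw <- denoiser_forward(params, config$denoiser, vocab, batch, t_vec,
                           schedule$T,
                           cond = if (!is.null(cond_vals)) cond_vals[ch])
    bl <- batch_loss(fw, idx_list[ch], idxt, t_vec, schedule,
                     config$loss_weights, vocab)
    total <- total + as.numeric(ad_value(bl$loss)) * B
  }
  total / length(idx_list)
}

#' Train a diffusion model on a molecule corpus
#'
#' Builds the vocabulary and fixed graph size from the corpus, constructs
#' the mask-and-replace schedule, then optimizes the denoiser with AdamW:
#' per molecule and step a timestep is drawn uniformly from `1..T`, the
#' graph is corrupted, and the weighted variational-bound plus
#' cross-entropy loss is backpropagated (global gradient norm clipped). The
#' returned checkpoint carries the parameters with the best validation
#' loss.
#'
#' @param smiles training molecules (character vector; need not be unique —
#'   multiplicity encodes the target distribution).
#' @param config a [train_config()].
#' @param properties optional data.frame of numeric per-molecule property
#'   columns aligned with `smiles` (required when `config$condition_on` is
#'   set).
#' @param valid_smiles validation molecules (defaults to the training set).
#' @param valid_properties property table for `valid_smiles`.
#' @return object of class `moldiff_model`: `params` (best checkpoint),
#'   `final_params`, `config` (the denoiser config), `train_config`,
#'   `vocab`, `schedule`, `n`, `cond_stats`, `train_canonical`, and a
#'   per-epoch `log` data.frame.
#' @export
train_model <- function(smiles, config = train_config(), properties = NULL,
                        valid_smiles = NULL, valid_properties = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  set.seed(config$seed)
  if (is.null(valid_smiles)) {
    valid_smiles <- smiles
    valid_properties <- properties
  }
  tabs <- molecule_tables(smiles)
  vtabs <- molecule_tables(valid_smiles)
  vocab <- build_vocabulary(unique(c(smiles, valid_smiles)))
  n <- max(vapply(c(tabs, vtabs), function(m) nrow(m$atoms), integer(1))) +
    config$n_headroom
  schedule <- make_schedule(config$T_steps, channel_K(vocab),
                            kind = config$schedule_kind,
                            mask_fraction_final = config$mask_fraction_final,
                            uniform_weight = config$uniform_weight)
  idx_train <- lapply(tabs, function(m) {
    graph_indices(encode_molecule_table(m, vocab, n))
  })
  idx_valid <- lapply(vtabs, function(m) {
    graph_indices(encode_molecule_table(m, vocab, n))
  })
  cond_train <- cond_valid <- NULL
  cond_stats <- NULL
  dconf <- config$denoiser
  if (!is.null(config$condition_on)) {
    if (dconf$condition_dim == 0) {
      dconf$condition_dim <- 16L  # conditional head width
    }
    getcol <- function(props, who) {
      if (is.null(props) || is.null(props[[config$condition_on]])) {
        stop("condition_on = '", config$condition_on,
             "' requires a matching ", who, " property column")
      }
      as.numeric(props[[config$condition_on]])
    }
    raw_train <- getcol(properties, "training")
    raw_valid <- getcol(valid_properties, "validation")
    cond_stats <- list(mean = mean(raw_train),
                       sd = max(stats::sd(raw_train), 1e-8))
    cond_train <- (raw_train - cond_stats$mean) / cond_stats$sd
    cond_valid <- (raw_valid - cond_stats$mean) / cond_stats$sd
  }
  params <- init_denoiser(dconf, vocab)
  opt <- adamw_init(params)
  config$denoiser <- dconf
  model_of <- function(p) {
    structure(list(params = p, config = dconf, train_config = config,
                   vocab = vocab, schedule = schedule, n = as.integer(n),
                   cond_stats = cond_stats,
                   condition_on = config$condition_on,
                   train_canonical = unique(canonical_smiles(smiles))),
              class = "moldiff_model")
  }
  eval_seed <- config$seed + 997L
  best_val <- validation_loss(params, config, vocab, schedule, idx_valid,
                              cond_valid, eval_seed)
  best_params <- params
  log <- data.frame()
  N <- length(idx_train)
  steps_per_epoch <- ceiling(N / config$batch_size)
  total_steps <- max(1L, config$epochs * steps_per_epoch)
  step_no <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    chunks <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0; ep_comp <- NULL
    for (ch in chunks) {
      step_no <- step_no + 1L
      step <- training_step(params, opt, config, vocab, schedule,
                            idx_train[ch],
                            if (!is.null(cond_train)) cond_train[ch],
                            lr = lr_at(config$lr, step_no, total_steps))
      params <- step$params; opt <- step$opt
      ep_loss <- ep_loss + step$loss * length(ch)
      ep_comp <- if (is.null(ep_comp)) step$components * length(ch) else
        ep_comp + step$components * length(ch)
    }
    val <- validation_loss(params, config, vocab, schedule, idx_valid,
                           cond_valid, eval_seed)
    if (val <= best_val) {
      best_val <- val
      best_params <- params
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / N,
                                 valid_loss = val,
                                 t(ep_comp / N)))
  }
  model <- model_of(best_params)
  model$final_params <- params
  model$best_valid_loss <- best_val
  model$log <- log
  model
}

#' @export
print.moldiff_model <- function(x, ...) {
  cat("moldiff model: n =", x$n, "| T =", x$schedule$T,
      "| layers =", x$config$layers, "| hidden =", x$config$hidden,
      if (x$config$condition_dim > 0) paste("| conditional on",
                                            x$condition_on) else "", "\n")
  if (nrow(x$log %||% data.frame())) {
    cat("  epochs:", nrow(x$log), " best validation loss:",
        signif(x$best_valid_loss, 4), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The checkpoint is self-contained: parameters, denoiser configuration,
#' vocabulary and noise schedule, sufficient to resume sampling with no
#' other inputs.
#'
#' @param model a `moldiff_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "moldiff_model"))
  model
}
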