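# Graph-transformer denoiser with random node initialization (RNI).
#
# Node features = one-hot(atom) || one-hot(charge) || RNI noise || sinusoidal
# time embedding || (condition embedding). Each layer runs full pairwise
# multi-head attention with an additive edge-feature bias on the scores,
# a position-wise feed-forward block, and a symmetric edge-stream update
# from incident node features; pre-layer-norm with residual connections
# throughout. Output heads produce normalized distributions over *ordinary*
# categories only (the network never predicts <MASK>). Because every edge
# operation is symmetric in (i, j), edge logits are equal across mirrored
# entries by construction; they are still mirror-averaged before the softmax
# so the symmetry is exact to the last bit.

#' Denoiser hyper-parameters
#'
#' Defaults follow the reference training setup (6 layers, hidden size 256,
#' 8 attention heads, dropout 0.1); tests and desk-scale presets use much
#' smaller instances.
#'
#' @param layers transformer depth.
#' @param hidden node stream width (divisible by `heads`).
#' @param heads attention heads.
#' @param dropout dropout rate in `[0, 1)`, applied to the attention and
#'   feed-forward residual branches during training.
#' @param rni_dim width of the standard-normal random node features,
#'   resampled every forward pass (both training and sampling).
#' @param time_embed_dim sinusoidal timestep embedding width (even).
#' @param condition_dim width of the property-condition embedding; 0 gives
#'   an unconditional model.
#' @param edge_hidden edge stream width (default `hidden / 2`).
#' @return a `denoiser_config` list.
#' @export
denoiser_config <- function(layers = 6, hidden = 256, heads = 8,
                            dropout = 0.1, rni_dim = 8, time_embed_dim = 16,
                            condition_dim = 0, edge_hidden = hidden / 2) {
  stopifnot(layers >= 1, hidden >= 1, heads >= 1, hidden %% heads == 0,
            dropout >= 0, dropout < 1, rni_dim >= 0,
            time_embed_dim >= 2, time_embed_dim %% 2 == 0,
            condition_dim >= 0, edge_hidden >= 1)
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads), dropout = dropout,
                 rni_dim = as.integer(rni_dim),
                 time_embed_dim = as.integer(time_embed_dim),
                 condition_dim = as.integer(condition_dim),
                 edge_hidden = as.integer(edge_hidden)),
            class = "denoiser_config")
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros_row <- function(k) matrix(0, 1, k)
ones_row <- function(k) matrix(1, 1, k)

#' Initialize denoiser parameters (Xavier)
#'
#' @param config a [denoiser_config()].
#' @param vocab the channel vocabulary (fixes input/output widths).
#' @return named list of parameter matrices.
#' @export
init_denoiser <- function(config, vocab) {
  h <- config$hidden; he <- config$edge_hidden
  dh <- h %/% config$heads
  d_in <- (vocab$K_A + 1L) + (vocab$K_C + 1L) + config$rni_dim +
    config$time_embed_dim + config$condition_dim
  d_e <- vocab$K_E + 1L
  p <- list(W_in = xavier(d_in, h), b_in = zeros_row(h),
            We_in = xavier(d_e, he), be_in = zeros_row(he))
  if (config$condition_dim > 0) {
    p$wc <- xavier(1, config$condition_dim)
    p$bc <- zeros_row(config$condition_dim)
  }
  for (l in seq_len(config$layers)) {
    nm <- function(s) paste0(s, l)
    p[[nm("ln1_g")]] <- ones_row(h); p[[nm("ln1_b")]] <- zeros_row(h)
    for (k in seq_len(config$heads)) {
      p[[paste0("Wq", l, "_", k)]] <- xavier(h, dh)
      p[[paste0("Wk", l, "_", k)]] <- xavier(h, dh)
      p[[paste0("Wv", l, "_", k)]] <- xavier(h, dh)
    }
    p[[nm("Wo")]] <- xavier(h, h); p[[nm("bo")]] <- zeros_row(h)
    p[[nm("lne_g")]] <- ones_row(he); p[[nm("lne_b")]] <- zeros_row(he)
    p[[nm("Watt")]] <- xavier(he, config$heads)
    p[[nm("Wea")]] <- xavier(he, h); p[[nm("bea")]] <- zeros_row(h)
    p[[nm("ln2_g")]] <- ones_row(h); p[[nm("ln2_b")]] <- zeros_row(h)
    p[[nm("W1")]] <- xavier(h, 2 * h); p[[nm("b1")]] <- zeros_row(2 * h)
    p[[nm("W2")]] <- xavier(2 * h, h); p[[nm("b2")]] <- zeros_row(h)
    p[[nm("We1")]] <- xavier(2 * h + he, he); p[[nm("be1")]] <- zeros_row(he)
    p[[nm("We2")]] <- xavier(he, he); p[[nm("be2")]] <- zeros_row(he)
  }
  p$lnf_g <- ones_row(h); p$lnf_b <- zeros_row(h)
  p$lnef_g <- ones_row(he); p$lnef_b <- zeros_row(he)
  p$W_atom <- xavier(h, vocab$K_A); p$b_atom <- zeros_row(vocab$K_A)
  p$W_charge <- xavier(h, vocab$K_C); p$b_charge <- zeros_row(vocab$K_C)
  p$W_edge <- xavier(he, vocab$K_E); p$b_edge <- zeros_row(vocab$K_E)
  p
}

# sinusoidal embedding of t / T with geometric frequencies
time_embedding <- function(t, T_steps, dim) {
  half <- dim %/% 2
  x <- t / T_steps
  w <- pi * 2^(seq_len(half) - 1)
  c(sin(w * x), cos(w * x))
}

# Batch container: index graphs -> stacked one-hot matrices plus the index
# maps used by the edge stream. Edge rows are column-major per graph:
# row (b-1)*n^2 + (j-1)*n + i is the (i, j) entry of graph b.
make_batch <- function(idx_list, vocab) {
  B <- length(idx_list)
  n <- length(idx_list[[1]]$a)
  Aoh <- onehot_matrix(unlist(lapply(idx_list, `[[`, "a")), vocab$K_A + 1L)
  Coh <- onehot_matrix(unlist(lapply(idx_list, `[[`, "c")), vocab$K_C + 1L)
  Eoh <- onehot_matrix(unlist(lapply(idx_list, function(g) as.vector(g$e))),
                       vocab$K_E + 1L)
  ii <- rep(seq_len(n), times = n)   # i of each within-graph edge row
  jj <- rep(seq_len(n), each = n)
  off_node <- rep((seq_len(B) - 1L) * n, each = n * n)
  idx_i <- off_node + rep(ii, B)
  idx_j <- off_node + rep(jj, B)
  mirror <- rep((seq_len(B) - 1L) * n * n, each = n * n) +
    rep((ii - 1L) * n + jj, B)
  # linear position of edge row (b, i, j) in the (B n) x (B n) attention
  # score matrix, and the -Inf template masking cross-graph attention
  att_pos <- (idx_j - 1L) * (B * n) + idx_i
  att_template <- matrix(-Inf, B * n, B * n)
  att_template[att_pos] <- 0
  list(B = B, n = n, Aoh = Aoh, Coh = Coh, Eoh = Eoh,
       idx_i = idx_i, idx_j = idx_j, mirror = mirror,
       att_pos = att_pos, att_template = att_template)
}

dropout_mask <- function(dim1, dim2, rate) {
  matrix(stats::rbinom(dim1 * dim2, 1, 1 - rate) / (1 - rate), dim1, dim2)
}

# Core forward pass over a batch. `params` may hold plain matrices (fast,
# no-gradient path) or autodiff nodes (training path). Returns stacked
# probability matrices over ordinary categories.
denoiser_forward <- function(params, config, vocab, batch, t_vec, T_steps,
                             cond = NULL, rni = NULL, training = FALSE) {
  B <- batch$B; n <- batch$n
  h <- config$hidden; heads <- config$heads
  dh <- h %/% heads
  if (length(t_vec) == 1) t_vec <- rep(t_vec, B)
  stopifnot(length(t_vec) == B, all(t_vec >= 1), all(t_vec <= T_steps))
  if (is.null(rni)) {
    rni <- matrix(stats::rnorm(B * n * config$rni_dim), B * n, config$rni_dim)
  }
  temb_g <- t(vapply(t_vec, time_embedding, numeric(config$time_embed_dim),
                     T_steps = T_steps, dim = config$time_embed_dim))
  rep_nodes <- rep(seq_len(B), each = n)
  temb <- temb_g[rep_nodes, , drop = FALSE]
  feats <- list(batch$Aoh, batch$Coh)
  if (config$rni_dim > 0) feats <- c(feats, list(rni))
  feats <- c(feats, list(temb))
  if (config$condition_dim > 0) {
    if (is.null(cond)) stop("conditional model requires a condition value")
    cmat <- matrix(as.numeric(cond), B, 1)
    cemb <- ad_tanh(ad_add(ad_mm(cmat, params$wc), params$bc))
    feats <- c(feats, list(ad_gather_rows(cemb, rep_nodes)))
  }
  H <- ad_add(ad_mm(ad_cbind(feats), params$W_in), params$b_in)
  Eh <- ad_add(ad_mm(batch$Eoh, params$We_in), params$be_in)
  drop_rate <- if (training) config$dropout else 0
  for (l in seq_len(config$layers)) {
    P <- function(s) params[[paste0(s, l)]]
    Hn <- ad_layernorm_rows(H, P("ln1_g"), P("ln1_b"))
    En <- ad_layernorm_rows(Eh, P("lne_g"), P("lne_b"))
    bias_all <- ad_mm(En, P("Watt"))
    head_outs <- vector("list", heads)
    for (k in seq_len(heads)) {
      Qk <- ad_mm(Hn, params[[paste0("Wq", l, "_", k)]])
      Kk <- ad_mm(Hn, params[[paste0("Wk", l, "_", k)]])
      Vk <- ad_mm(Hn, params[[paste0("Wv", l, "_", k)]])
      # all graphs at once: block-diagonal scores; the scatter template
      # holds -Inf outside the blocks, so cross-graph attention is zero.
      # The edge bias is symmetric (the edge stream is), so its
      # orientation in the score matrix is immaterial.
      bias <- ad_scatter_positions(ad_slice_cols(bias_all, k),
                                   batch$att_pos, batch$att_template)
      scores <- ad_add(ad_scale(ad_mm(Qk, ad_t(Kk)), 1 / sqrt(dh)), bias)
      head_outs[[k]] <- ad_mm(ad_softmax_rows(scores), Vk)
    }
    O <- ad_add(ad_mm(ad_cbind(head_outs), P("Wo")), P("bo"))
    if (drop_rate > 0) {
      O <- ad_hadamard(O, dropout_mask(B * n, h, drop_rate))
    }
    H <- ad_add(H, O)
    # direct edge-to-node message: each node aggregates its incident edge
    # features (mean over partners), the strongest evidence about whether
    # a row is a real atom and what bonds it carries
    AggE <- ad_scale(ad_rowsum_groups(En, batch$idx_i, B * n), 1 / n)
    H <- ad_add(H, ad_add(ad_mm(AggE, P("Wea")), P("bea")))
    Hn2 <- ad_layernorm_rows(H, P("ln2_g"), P("ln2_b"))
    FF <- ad_add(ad_mm(ad_relu(ad_add(ad_mm(Hn2, P("W1")), P("b1"))),
                       P("W2")), P("b2"))
    if (drop_rate > 0) {
      FF <- ad_hadamard(FF, dropout_mask(B * n, h, drop_rate))
    }
    H <- ad_add(H, FF)
    Hi <- ad_gather_rows(H, batch$idx_i)
    Hj <- ad_gather_rows(H, batch$idx_j)
    Z <- ad_cbind(list(ad_add(Hi, Hj), ad_hadamard(Hi, Hj), En))
    EF <- ad_add(ad_mm(ad_relu(ad_add(ad_mm(Z, P("We1")), P("be1"))),
                       P("We2")), P("be2"))
    Eh <- ad_add(Eh, EF)
  }
  Hf <- ad_layernorm_rows(H, params$lnf_g, params$lnf_b)
  Ef <- ad_layernorm_rows(Eh, params$lnef_g, params$lnef_b)
  atom_logits <- ad_add(ad_mm(Hf, params$W_atom), params$b_atom)
  charge_logits <- ad_add(ad_mm(Hf, params$W_charge), params$b_charge)
  edge_logits <- ad_add(ad_mm(Ef, params$W_edge), params$b_edge)
  edge_logits <- ad_scale(ad_add(edge_logits,
                                 ad_gather_rows(edge_logits, batch$mirror)),
                          0.5)
  list(atom = ad_softmax_rows(atom_logits),
       charge = ad_softmax_rows(charge_logits),
       edge = ad_softmax_rows(edge_logits),
       B = B, n = n)
}

#' Predict clean-category distributions for a noisy graph
#'
#' Runs the graph transformer on one (possibly masked) graph at timestep `t`
#' and returns normalized probability distributions over the ordinary (clean)
#' categories for every atom, charge, and edge entry; `<MASK>` receives no
#' probability mass. Random node initialization features are drawn fresh from
#' a standard normal unless `rni_noise` is supplied (pass them explicitly for
#' reproducibility/equivariance checks).
#'
#' @param model a trained or initialized model/checkpoint
#'   (list with `params`, `config`, `vocab`, `schedule`, optionally
#'   `cond_stats`), e.g. from [train_model()].
#' @param g_t a `mol_graph`, possibly containing `<MASK>` categories.
#' @param t timestep in `1..T`.
#' @param condition raw property value for conditional models (standardized
#'   internally using the model's training statistics).
#' @param rni_noise optional `n x rni_dim` matrix of node noise features.
#' @return list of class `denoiser_output`: `atom_probs` (`n x K_A`),
#'   `charge_probs` (`n x K_C`), `edge_probs` (`n x n x K_E`, symmetric).
#' @export
predict_clean <- function(model, g_t, t, condition = NULL, rni_noise = NULL) {
  config <- model$config; vocab <- model$vocab
  if (t < 1 || t > model$schedule$T) {
    stop("t out of range [1, ", model$schedule$T, "]")
  }
  if (config$condition_dim > 0 && is.null(condition)) {
    stop("conditional model requires a condition value")
  }
  cond <- if (config$condition_dim > 0) {
    standardize_condition(condition, model$cond_stats)
  }
  idx <- graph_indices(g_t)
  batch <- make_batch(list(idx), vocab)
  out <- denoiser_forward(model$params, config, vocab, batch, t,
                          model$schedule$T, cond = cond, rni = rni_noise)
  n <- g_t$n
  structure(list(atom_probs = ad_value(out$atom),
                 charge_probs = ad_value(out$charge),
                 edge_probs = array(ad_value(out$edge),
                                    dim = c(n, n, vocab$K_E))),
            class = "denoiser_output")
}

standardize_condition <- function(x, stats) {
  if (is.null(stats)) return(as.numeric(x))
  (as.numeric(x) - stats$mean) / stats$sd
}
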