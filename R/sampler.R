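# Reverse-diffusion generation.
#
# Sampling starts from the all-<MASK> graph at t = T and repeatedly draws
# G_{t-1} from the reverse distribution (the closed-form posterior mixed
# over the denoiser's clean-category prediction). Edges are drawn on the
# strictly-lower triangle and mirrored; the diagonal stays "none". At the
# final step the clean graph is the argmax of p_theta(x_0 | x_1) over
# ordinary categories, which guarantees a mask-free output. Scaffold
# optimization runs the same loop but overwrites the constrained entries
# with the start molecule's values after every reverse update.

# categorical draw per row of a row-stochastic matrix
sample_rows <- function(P) {
  if (nrow(P) == 0) return(integer(0))
  k <- ncol(P)
  upper_ones <- matrix(1, k, k)
  upper_ones[lower.tri(upper_ones)] <- 0
  cs <- P %*% upper_ones  # row-wise cumulative sums
  u <- stats::runif(nrow(P))
  as.integer(rowSums(cs < u) + 1L)
}

#' Reverse transition distributions for a noisy graph
#'
#' Mixes the closed-form posterior over the denoiser's predicted clean
#' categories: `p(x_{t-1} | x_t) = sum_x0 q(x_{t-1} | x_t, x0) p_theta(x0)`.
#'
#' @param g_t noisy `mol_graph` at step `t`.
#' @param t timestep in `1..T`.
#' @param out a `denoiser_output` for `g_t`.
#' @param schedule the `noise_schedule`.
#' @return list with `atom` (`n x (K_A+1)`), `charge` (`n x (K_C+1)`) and
#'   `edge` (`n x n x (K_E+1)`) per-entry distributions over `x_{t-1}`.
#' @export
reverse_distribution <- function(g_t, t, out, schedule) {
  idx <- graph_indices(g_t)
  n <- g_t$n
  pm <- output_channel_matrices(out, n)
  atom <- mix_posterior(pm$atom, idx$a, t, "A", schedule)
  charge <- mix_posterior(pm$charge, idx$c, t, "C", schedule)
  edge_flat <- mix_posterior(pm$edge, as.vector(idx$e), t, "E", schedule)
  # the diagonal is fixed "none" by convention (never corrupted, never
  # sampled); report it as a point mass rather than a forward-process
  # posterior, which is undefined there at full mask
  diag_rows <- (seq_len(n) - 1L) * n + seq_len(n)
  edge_flat[diag_rows, ] <- 0
  edge_flat[diag_rows, 1L] <- 1
  list(atom = atom, charge = charge,
       edge = array(edge_flat, dim = c(n, n, ncol(edge_flat))))
}

# rows of `probs` (m x K) -> rows over x_{t-1} (m x (K+1)) given current
# categories xt
mix_posterior <- function(probs, xt, t, channel, schedule) {
  Ms <- posterior_matrices(t, channel, schedule)
  K1 <- nrow(Ms[[1]])
  out <- matrix(0, length(xt), K1)
  for (v in sort(unique(xt))) {
    rows <- xt == v
    out[rows, ] <- probs[rows, , drop = FALSE] %*% t(Ms[[v]])
  }
  out
}

all_mask_indices <- function(n, vocab) {
  e <- matrix(mask_index(vocab, "E"), n, n)
  diag(e) <- 1L
  list(a = rep(mask_index(vocab, "A"), n),
       c = rep(mask_index(vocab, "C"), n), e = e)
}

# One batched reverse trajectory over a list of index graphs. `clamp` is
# NULL or list(a, c, e, n_s) — scaffold values written after every update.
# `rni_samples` forward passes are averaged per step: a Monte-Carlo
# estimate of the model's RNI-marginal predictor. Returns
# list(graphs = idx list, clamp_ok = logical).
reverse_trajectory <- function(model, B, condition = NULL, clamp = NULL,
                               rni_samples = 1) {
  vocab <- model$vocab; schedule <- model$schedule
  config <- model$config
  n <- model$n
  Tt <- schedule$T
  state <- replicate(B, all_mask_indices(n, vocab), simplify = FALSE)
  cond <- NULL
  if (config$condition_dim > 0) {
    if (is.null(condition)) stop("conditional model requires a condition value")
    cond <- rep(standardize_condition(condition, model$cond_stats), B)
  }
  low <- lower_tri_edge_rows(n)
  clamp_ok <- TRUE
  apply_clamp <- function(g) {
    ns <- clamp$n_s
    g$a[seq_len(ns)] <- clamp$a
    g$c[seq_len(ns)] <- clamp$c
    g$e[seq_len(ns), seq_len(ns)] <- clamp$e
    g
  }
  if (!is.null(clamp)) state <- lapply(state, apply_clamp)
  for (t in seq(Tt, 1)) {
    batch <- make_batch(state, vocab)
    fw <- denoiser_forward(model$params, config, vocab, batch, t, Tt,
                           cond = cond)
    if (rni_samples > 1) {
      for (k in seq_len(rni_samples - 1)) {
        f2 <- denoiser_forward(model$params, config, vocab, batch, t, Tt,
                               cond = cond)
        fw$atom <- fw$atom + f2$atom
        fw$charge <- fw$charge + f2$charge
        fw$edge <- fw$edge + f2$edge
      }
      fw$atom <- fw$atom / rni_samples
      fw$charge <- fw$charge / rni_samples
      fw$edge <- fw$edge / rni_samples
    }
    xa <- unlist(lapply(state, `[[`, "a"))
    xc <- unlist(lapply(state, `[[`, "c"))
    xe_low <- unlist(lapply(state, function(g) g$e[low]))
    er <- as.vector(vapply(seq_len(B), function(b) (b - 1L) * n * n + low,
                           integer(length(low))))
    if (t > 1) {
      na <- sample_rows(mix_posterior(fw$atom, xa, t, "A", schedule))
      nc <- sample_rows(mix_posterior(fw$charge, xc, t, "C", schedule))
      ne <- sample_rows(mix_posterior(fw$edge[er, , drop = FALSE], xe_low,
                                      t, "E", schedule))
    } else {
      # final step: argmax of p_theta(x0 | x1) over ordinary categories
      na <- max.col(fw$atom, ties.method = "first")
      nc <- max.col(fw$charge, ties.method = "first")
      ne <- max.col(fw$edge[er, , drop = FALSE], ties.method = "first")
    }
    for (b in seq_len(B)) {
      g <- state[[b]]
      g$a <- na[((b - 1L) * n + 1L):(b * n)]
      g$c <- nc[((b - 1L) * n + 1L):(b * n)]
      ev <- ne[((b - 1L) * length(low) + 1L):(b * length(low))]
      g$e[low] <- ev
      g$e <- t(g$e)
      g$e[low] <- ev  # mirror lower triangle to the upper
      if (!is.null(clamp)) g <- apply_clamp(g)
      state[[b]] <- g
    }
    if (!is.null(clamp)) {
      ns <- clamp$n_s
      ok <- all(vapply(state, function(g) {
        all(g$a[seq_len(ns)] == clamp$a) && all(g$c[seq_len(ns)] == clamp$c) &&
          all(g$e[seq_len(ns), seq_len(ns)] == clamp$e)
      }, logical(1)))
      clamp_ok <- clamp_ok && ok
    }
  }
  list(graphs = state, clamp_ok = clamp_ok)
}

#' Generate molecules by reverse diffusion
#'
#' @param model trained model/checkpoint from [train_model()].
#' @param n_molecules number of samples (failed decodes included in the
#'   output as `NA`).
#' @param condition raw property value for conditional models.
#' @param seed optional seed fixing the whole run.
#' @param batch_size reverse trajectories run per forward batch.
#' @param rni_samples forward passes averaged per reverse step (Monte-Carlo
#'   marginalization over the random node features; values above 1 give a
#'   less noisy estimate of the model's predictive distribution at
#'   proportional cost).
#' @return list with `smiles` (length `n_molecules`, `NA_character_` for
#'   invalid generations) and `graphs` (list of clean `mol_graph`s).
#' @export
sample_molecules <- function(model, n_molecules, condition = NULL,
                             seed = NULL, batch_size = 100,
                             rni_samples = 1) {
  stopifnot(n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  vocab <- model$vocab
  sizes <- diff(unique(c(seq(0, n_molecules, by = batch_size), n_molecules)))
  graphs <- list()
  for (B in sizes) {
    traj <- reverse_trajectory(model, B, condition = condition,
                               rni_samples = rni_samples)
    graphs <- c(graphs, traj$graphs)
  }
  gs <- lapply(graphs, function(g) graph_from_indices(g$a, g$c, g$e, vocab))
  list(smiles = graphs_to_smiles(gs, vocab), graphs = gs)
}

#' Scaffold constraint for inpainting optimization
#'
#' Places the start molecule on the first `n_s` rows of the fixed-size graph
#' and records the 0/1 masks (here: index sets) that are clamped at every
#' reverse step: the first `n_s` atom and charge rows and the leading
#' `n_s x n_s` edge block.
#'
#' @param start SMILES of the start molecule.
#' @param vocab model vocabulary.
#' @param n model graph size (heavy atoms of `start` must be `<= n`).
#' @return list with the scaffold graph values (`a`, `c`, `e`) and `n_s`.
#' @export
scaffold_constraint <- function(start, vocab, n) {
  g <- smiles_to_graph(start, vocab, n)  # errors if start is too large
  idx <- graph_indices(g)
  ns <- g$n_real
  list(a = idx$a[seq_len(ns)], c = idx$c[seq_len(ns)],
       e = idx$e[seq_len(ns), seq_len(ns), drop = FALSE], n_s = ns,
       start = start)
}

#' Optimize a molecule by scaffold-preserving generation
#'
#' Runs conditional reverse diffusion while clamping the start molecule's
#' atoms, charges and internal bonds on the first `n_s` rows after every
#' reverse step, so each generated molecule extends the start structure
#' (atoms can only be added, never removed).
#'
#' @param model trained (typically conditional) model.
#' @param start SMILES of the molecule to extend.
#' @param condition target property value (required for conditional models).
#' @param n_samples number of optimization samples.
#' @param seed optional seed.
#' @param batch_size trajectories per forward batch.
#' @param rni_samples forward passes averaged per reverse step.
#' @return list with `smiles`, `graphs`, and `scaffold_preserved` (TRUE if
#'   the constrained entries matched the scaffold at every reverse step of
#'   every trajectory — checked at graph level, before decoding).
#' @export
optimize_molecules <- function(model, start, condition = NULL, n_samples = 1,
                               seed = NULL, batch_size = 100,
                               rni_samples = 1) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- model$vocab
  clamp <- scaffold_constraint(start, vocab, model$n)
  sizes <- diff(unique(c(seq(0, n_samples, by = batch_size), n_samples)))
  graphs <- list(); ok <- TRUE
  for (B in sizes) {
    traj <- reverse_trajectory(model, B, condition = condition, clamp = clamp,
                               rni_samples = rni_samples)
    graphs <- c(graphs, traj$graphs)
    ok <- ok && traj$clamp_ok
  }
  gs <- lapply(graphs, function(g) graph_from_indices(g$a, g$c, g$e, vocab))
  list(smiles = graphs_to_smiles(gs, vocab), graphs = gs,
       scaffold_preserved = ok)
}
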