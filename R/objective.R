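# Training objective: per-channel variational-bound terms (KL between the
# closed-form posterior and the model's reverse mixture) plus auxiliary
# cross-entropy on the clean categories, combined with configurable weights.
#
# Channel entry sets: every atom row, every charge row, and every
# strictly-lower-triangular edge entry (the upper triangle is a mirror and
# the diagonal is fixed). VLB terms are sums over entries; CE terms are
# means. All logs are floored at 1e-30: absorbing-state posteriors contain
# exact zeros.

LOG_FLOOR <- 1e-30

#' Default loss weights
#'
#' Edge terms are up-weighted five-fold relative to the charge terms (edges
#' number n^2 but are dominated by "none"), and the atom terms carry double
#' weight: sample fidelity is most sensitive to atom-identity and
#' atom-count errors, and reverse sampling consumes the clean-category
#' (cross-entropy-trained) prediction directly, so the atom cross-entropy
#' matches its bound weight instead of entering at half strength.
#'
#' @return named numeric vector `(vlb_A, vlb_C, vlb_E, ce_A, ce_C, ce_E)`.
#' @export
default_loss_weights <- function() {
  c(vlb_A = 2, vlb_C = 1, vlb_E = 5, ce_A = 2, ce_C = 0.5, ce_E = 2.5)
}

lower_tri_edge_rows <- function(n) {
  ii <- rep(seq_len(n), times = n)
  jj <- rep(seq_len(n), each = n)
  which(ii > jj)  # row (j-1)*n + i of the column-major edge matrix
}

# Sum over entries of KL[ q(x_{t-1} | x_t, x0) || p_theta(x_{t-1} | x_t) ]
# for one channel; at t = 1 this degenerates to -log p_theta(x0 | x1).
# `probs` may be a plain matrix or an autodiff node (m x K, ordinary cats).
channel_vlb <- function(probs, x0, xt, t, channel, schedule) {
  m <- length(x0)
  if (m == 0) return(matrix(0, 1, 1))
  if (t == 1) {
    W <- matrix(0, m, ncol(ad_value(probs)))
    W[cbind(seq_len(m), x0)] <- -1
    return(ad_sum_weighted(ad_log(probs, LOG_FLOOR), W))
  }
  Ms <- posterior_matrices(t, channel, schedule)
  terms <- list(); weights <- numeric(0)
  const <- 0
  for (v in sort(unique(xt))) {
    rows <- which(xt == v)
    M <- Ms[[v]]                                   # (K+1) x K over x0
    Qpost <- t(M[, x0[rows], drop = FALSE])        # m_v x (K+1), constant
    Prev <- ad_mm(ad_gather_rows(probs, rows), t(M))
    const <- const + sum(ifelse(Qpost > 0, Qpost * log(Qpost), 0))
    terms <- c(terms, list(ad_sum_weighted(ad_log(Prev, LOG_FLOOR), -Qpost)))
    weights <- c(weights, 1)
  }
  ad_scalar_combine(c(terms, list(matrix(const, 1, 1))), c(weights, 1))
}

# mean negative log-probability of the true clean categories
channel_ce <- function(probs, x0) {
  m <- length(x0)
  if (m == 0) return(matrix(0, 1, 1))
  W <- matrix(0, m, ncol(ad_value(probs)))
  W[cbind(seq_len(m), x0)] <- -1 / m
  ad_sum_weighted(ad_log(probs, LOG_FLOOR), W)
}

output_channel_matrices <- function(out, n) {
  K_E <- dim(out$edge_probs)[3]
  list(atom = out$atom_probs, charge = out$charge_probs,
       edge = matrix(out$edge_probs, n * n, K_E))
}

#' Variational-bound terms for one corrupted graph
#'
#' For `t >= 2`, each channel's term is the sum over its entries of the KL
#' divergence between the closed-form posterior `q(x_{t-1} | x_t, x_0)` and
#' the model's reverse distribution (the posterior mixed over the predicted
#' clean-category probabilities). For `t = 1` it is the
#' reconstruction term `-log p_theta(x_0 | x_1)` summed over entries. The
#' prior term `KL[q(x_T | x_0) || p(x_T)]` against the all-mask terminal
#' distribution is returned as the constant attribute `prior` (zero for
#' schedules that mask fully); it is reported, never differentiated.
#'
#' @param g0 clean `mol_graph`.
#' @param g_t its corruption at step `t` (from [corrupt_graph()]).
#' @param t timestep in `1..T`.
#' @param out a `denoiser_output` for `g_t`.
#' @param schedule the `noise_schedule`.
#' @return named numeric vector `c(A=, C=, E=)` with attribute `prior`.
#' @export
vlb_terms <- function(g0, g_t, t, out, schedule) {
  if (t < 1) stop("t must be >= 1")
  idx0 <- graph_indices(g0); idxt <- graph_indices(g_t)
  n <- g0$n
  low <- lower_tri_edge_rows(n)
  pm <- output_channel_matrices(out, n)
  res <- c(
    A = as.numeric(ad_value(channel_vlb(pm$atom, idx0$a, idxt$a, t, "A",
                                        schedule))),
    C = as.numeric(ad_value(channel_vlb(pm$charge, idx0$c, idxt$c, t, "C",
                                        schedule))),
    E = as.numeric(ad_value(channel_vlb(pm$edge[low, , drop = FALSE],
                                        idx0$e[low], idxt$e[low], t, "E",
                                        schedule))))
  attr(res, "prior") <- c(A = prior_term(idx0$a, "A", schedule),
                          C = prior_term(idx0$c, "C", schedule),
                          E = prior_term(idx0$e[low], "E", schedule))
  res
}

# KL[q(x_T | x0) || delta_mask] summed over entries (floored logs)
prior_term <- function(x0, channel, schedule) {
  if (length(x0) == 0) return(0)
  Qbar <- cumulative_matrix(schedule$T, channel, schedule)
  K1 <- nrow(Qbar)
  p_terminal <- c(rep(0, K1 - 1), 1)
  total <- 0
  for (v in sort(unique(x0))) {
    q <- Qbar[, v]
    kl <- sum(ifelse(q > 0, q * (log(q) - log(pmax(p_terminal, LOG_FLOOR))), 0))
    total <- total + kl * sum(x0 == v)
  }
  total
}

#' Auxiliary cross-entropy terms
#'
#' Mean negative log-probability of the true clean category over atoms,
#' charges, and strictly-lower-triangular edges.
#'
#' @inheritParams vlb_terms
#' @return named numeric vector `c(A=, C=, E=)`.
#' @export
ce_terms <- function(g0, out) {
  idx0 <- graph_indices(g0)
  n <- g0$n
  low <- lower_tri_edge_rows(n)
  pm <- output_channel_matrices(out, n)
  c(A = as.numeric(ad_value(channel_ce(pm$atom, idx0$a))),
    C = as.numeric(ad_value(channel_ce(pm$charge, idx0$c))),
    E = as.numeric(ad_value(channel_ce(pm$edge[low, , drop = FALSE],
                                       idx0$e[low]))))
}

#' Weighted total loss
#'
#' @param vlb,ce named numeric vectors `c(A=, C=, E=)` from [vlb_terms()]
#'   and [ce_terms()].
#' @param w weights `(vlb_A, vlb_C, vlb_E, ce_A, ce_C, ce_E)`; see
#'   [default_loss_weights()].
#' @return scalar loss.
#' @export
total_loss <- function(vlb, ce, w = default_loss_weights()) {
  stopifnot(length(w) == 6, all(w >= 0), any(w > 0))
  terms <- c(vlb[c("A", "C", "E")], ce[c("A", "C", "E")])
  bad <- !is.finite(terms)
  if (any(bad)) {
    stop("non-finite loss term(s): ",
         paste(c("vlb_A", "vlb_C", "vlb_E", "ce_A", "ce_C", "ce_E")[bad],
               collapse = ", "))
  }
  sum(unname(terms) * unname(w))
}

# Batched autodiff loss used by the trainer: graphs share one forward pass,
# each with its own timestep. Returns the scalar loss node plus detached
# per-component means for logging.
batch_loss <- function(fw, idx0_list, idxt_list, t_vec, schedule, weights,
                       vocab) {
  B <- fw$B; n <- fw$n
  low <- lower_tri_edge_rows(n)
  comp <- list(vlb_A = 0, vlb_C = 0, vlb_E = 0)
  terms <- list(); tw <- numeric(0)
  for (b in seq_len(B)) {
    nr <- ((b - 1L) * n + 1L):(b * n)
    er <- (b - 1L) * n * n + low
    pieces <- list(
      vlb_A = channel_vlb(ad_gather_rows(fw$atom, nr), idx0_list[[b]]$a,
                          idxt_list[[b]]$a, t_vec[b], "A", schedule),
      vlb_C = channel_vlb(ad_gather_rows(fw$charge, nr), idx0_list[[b]]$c,
                          idxt_list[[b]]$c, t_vec[b], "C", schedule),
      vlb_E = channel_vlb(ad_gather_rows(fw$edge, er), idx0_list[[b]]$e[low],
                          idxt_list[[b]]$e[low], t_vec[b], "E", schedule))
    for (nm in names(pieces)) {
      comp[[nm]] <- comp[[nm]] + as.numeric(ad_value(pieces[[nm]])) / B
    }
    terms <- c(terms, pieces)
    tw <- c(tw, unname(weights[c("vlb_A", "vlb_C", "vlb_E")]) / B)
  }
  x0a <- unlist(lapply(idx0_list, `[[`, "a"))
  x0c <- unlist(lapply(idx0_list, `[[`, "c"))
  x0e <- unlist(lapply(idx0_list, function(g) g$e[low]))
  all_er <- as.vector(vapply(seq_len(B),
                             function(b) (b - 1L) * n * n + low,
                             integer(length(low))))
  ce_A <- channel_ce(fw$atom, x0a)
  ce_C <- channel_ce(fw$charge, x0c)
  ce_E <- channel_ce(ad_gather_rows(fw$edge, all_er), x0e)
  terms <- c(terms, list(ce_A, ce_C, ce_E))
  tw <- c(tw, unname(weights[c("ce_A", "ce_C", "ce_E")]))
  loss <- ad_scalar_combine(terms, tw)
  comp$ce_A <- as.numeric(ad_value(ce_A))
  comp$ce_C <- as.numeric(ad_value(ce_C))
  comp$ce_E <- as.numeric(ad_value(ce_E))
  list(loss = loss, components = unlist(comp))
}
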