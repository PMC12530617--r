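# Forward corruption (graph noising) and the closed-form posterior
# q(x_{t-1} | x_t, x_0) of the mask-and-replace process.

# vectorized categorical draw: column cols[i] of the column-stochastic
# matrix Q gives the distribution of draw i
sample_from_columns <- function(Q, cols) {
  k <- nrow(Q)
  lower_ones <- matrix(1, k, k)
  lower_ones[upper.tri(lower_ones)] <- 0
  cs <- lower_ones %*% Q  # column-wise cumulative sums
  sel <- cs[, cols, drop = FALSE]
  u <- stats::runif(length(cols))
  as.integer(colSums(sel < rep(u, each = k)) + 1L)
}

# index-form corruption shared by corrupt_graph and the trainer.
# Atoms and charges row-wise; bonds on the strictly-lower triangle, then
# mirrored; the diagonal stays "none".
corrupt_indices <- function(a, ch, e, t, schedule) {
  if (t == 0) return(list(a = a, c = ch, e = e))
  QA <- cumulative_matrix(t, "A", schedule)
  QC <- cumulative_matrix(t, "C", schedule)
  QE <- cumulative_matrix(t, "E", schedule)
  n <- length(a)
  a2 <- sample_from_columns(QA, a)
  c2 <- sample_from_columns(QC, ch)
  e2 <- e
  if (n > 1) {
    low <- which(lower.tri(e))
    e2[low] <- sample_from_columns(QE, e[low])
    e2[upper.tri(e2)] <- t(e2)[upper.tri(e2)]
  }
  list(a = a2, c = c2, e = e2)
}

#' Corrupt a clean graph to diffusion step t
#'
#' Samples `G_t ~ q(G_t | G_0)` by drawing every atom and charge row from the
#' cumulative transition column of its clean category, and every
#' strictly-lower-triangular bond entry likewise, mirroring the result to the
#' upper triangle. The diagonal (self-bonds) is untouched. Randomness comes
#' from R's global RNG stream.
#'
#' @param g0 clean `mol_graph` (no `<MASK>` categories).
#' @param t timestep in `0..T`; `t = 0` returns `g0` unchanged.
#' @param schedule a `noise_schedule` whose channel widths match `g0`.
#' @return a (possibly masked) `mol_graph`.
#' @export
corrupt_graph <- function(g0, t, schedule) {
  idx <- graph_indices(g0)
  KA <- schedule_channel(schedule, "A")$K
  KC <- schedule_channel(schedule, "C")$K
  KE <- schedule_channel(schedule, "E")$K
  if (any(idx$a > KA) || any(idx$c > KC) || any(idx$e > KE)) {
    stop("corrupt_graph requires a clean graph (no <MASK> categories)")
  }
  if (t == 0) return(g0)
  out <- corrupt_indices(idx$a, idx$c, idx$e, t, schedule)
  n <- length(out$a)
  E <- array(0, dim = c(n, n, KE + 1L))
  E[cbind(rep(seq_len(n), n), rep(seq_len(n), each = n), as.vector(out$e))] <- 1
  new_mol_graph(onehot_matrix(out$a, KA + 1L), onehot_matrix(out$c, KC + 1L),
                E, g0$n_real)
}

#' Closed-form posterior q(x_{t-1} | x_t, x_0)
#'
#' Proportional to `Q_t[x_t, x_{t-1}] * Qbar_{t-1}[x_{t-1}, x_0]`, normalized
#' by `Qbar_t[x_t, x_0]`. If `x_t` is unreachable from `x_0` at step `t` the
#' normalizer is zero and a flagged zero vector is returned (attribute
#' `unreachable = TRUE`); this cannot occur in on-policy sampling.
#'
#' @param x_t observed category at step `t` (may be the mask index).
#' @param x0 clean category (ordinary; the mask index is a contract
#'   violation).
#' @param t timestep in `1..T`.
#' @param channel channel name in the schedule.
#' @param schedule a `noise_schedule`.
#' @return probability vector of length `K + 1` over `x_{t-1}`.
#' @export
posterior <- function(x_t, x0, t, channel, schedule) {
  ch <- schedule_channel(schedule, channel)
  if (x0 > ch$K) stop("x0 must be an ordinary category (clean data is never masked)")
  if (t < 1 || t > schedule$T) stop("t out of range [1, ", schedule$T, "]")
  M <- posterior_matrix(x_t, t, channel, schedule)
  out <- M[, x0]
  if (all(out == 0)) attr(out, "unreachable") <- TRUE
  out
}

# (K+1) x K matrix whose column x0 is q(x_{t-1} | x_t, x0); zero columns for
# unreachable (x_t, x0) pairs.
posterior_matrix <- function(x_t, t, channel, schedule) {
  ch <- schedule_channel(schedule, channel)
  K <- ch$K
  Qt <- transition_matrix(t, channel, schedule)
  Qbar_prev <- cumulative_matrix(t - 1, channel, schedule)
  Qbar_t <- cumulative_matrix(t, channel, schedule)
  lik <- Qt[x_t, ]                                  # over x_{t-1}
  U <- Qbar_prev[, seq_len(K), drop = FALSE] * lik  # rows x_{t-1}, cols x0
  norm <- Qbar_t[x_t, seq_len(K)]
  pos <- norm > 0
  U[, pos] <- sweep(U[, pos, drop = FALSE], 2, norm[pos], "/")
  U[, !pos] <- 0
  U
}

# all posterior matrices for one (t, channel): list indexed by x_t
posterior_matrices <- function(t, channel, schedule) {
  K <- schedule_channel(schedule, channel)$K
  lapply(seq_len(K + 1L), function(v) posterior_matrix(v, t, channel, schedule))
}
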