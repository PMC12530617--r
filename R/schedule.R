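# Mask-and-replace noise schedule and transition matrices.
#
# For a channel with K ordinary categories plus <MASK> (state K + 1), the
# per-step column-stochastic transition matrix is
#     Q_t[i, j] = q(x_t = i | x_{t-1} = j)
# with ordinary column j: alpha_t + beta_t on the diagonal, beta_t on every
# other ordinary entry, gamma_t on the mask entry; the mask column is the
# absorbing unit vector. Constraint: alpha_t + K beta_t + gamma_t = 1.
#
# Products of such matrices stay in the same family, giving the closed-form
# cumulative masses used throughout:
#   abar_t = alpha_t * abar_{t-1}
#   bbar_t = alpha_t * bbar_{t-1} + beta_t * abar_{t-1} + K beta_t bbar_{t-1}
#   gbar_t = 1 - abar_t - K * bbar_t
# so Qbar_t has abar_t + bbar_t on the ordinary diagonal, bbar_t off-diagonal
# and gbar_t in the mask row. The probability of never having been masked by
# step t is prod(1 - gamma_s), independent of the uniform component.

#' Construct a mask-and-replace noise schedule
#'
#' The default `"linear-mask"` schedule drives the *cumulative* mask mass
#' linearly up to `mask_fraction_final` at `t = T` (1 by default, so the
#' terminal state is all-`<MASK>`), with a small uniform-replacement
#' component: at each step the total uniform mass is
#' `uniform_weight * gamma_t`, capped so the keep probability stays
#' non-negative. A `"cosine-mask"` variant front-loads less corruption.
#'
#' @param T_steps number of diffusion steps (production-scale default
#'   elsewhere is 500; fixture presets use 24-50).
#' @param K named integer vector of ordinary category counts per channel,
#'   e.g. `c(A = 4, C = 1, E = 5)` or [channel_K()] of a vocabulary.
#' @param kind `"linear-mask"` (default) or `"cosine-mask"`.
#' @param mask_fraction_final cumulative mask mass at `t = T` (default 1).
#' @param uniform_weight per-step uniform mass as a fraction of the per-step
#'   mask mass (default 0.05: "mask-dominant" corruption).
#' @return object of class `noise_schedule`: `T`, per-channel lists with
#'   `K`, `alpha`, `beta`, `gamma` and cumulative `abar`, `bbar`, `gbar`.
#' @export
make_schedule <- function(T_steps, K, kind = "linear-mask",
                          mask_fraction_final = 1, uniform_weight = 0.05) {
  stopifnot(T_steps >= 1, mask_fraction_final > 0, mask_fraction_final <= 1,
            uniform_weight >= 0, length(K) >= 1, !is.null(names(K)))
  tt <- seq_len(T_steps)
  gbar_target <- switch(kind,
    "linear-mask" = mask_fraction_final * tt / T_steps,
    "cosine-mask" = mask_fraction_final * (1 - cos(pi * tt / (2 * T_steps))),
    stop("unknown schedule kind: ", kind))
  if (any(gbar_target > 1 + 1e-12)) stop("cumulative mask mass exceeds 1")
  # per-step mask probability recovering the cumulative target:
  # prod_{s<=t}(1 - gamma_s) = 1 - gbar_target_t
  surv <- c(1, 1 - gbar_target)
  gamma <- 1 - surv[-1] / surv[-length(surv)]
  gamma <- pmin(pmax(gamma, 0), 1)
  channels <- lapply(K, function(k) {
    k <- as.integer(k)
    u <- pmin(uniform_weight * gamma, 1 - gamma)  # total uniform mass
    beta <- u / k
    alpha <- 1 - gamma - u
    if (any(alpha < -1e-12)) stop("infeasible schedule: negative keep mass")
    alpha <- pmax(alpha, 0)
    abar <- cumprod(alpha)
    bbar <- numeric(T_steps)
    prev_a <- 1; prev_b <- 0
    for (t in tt) {
      bbar[t] <- alpha[t] * prev_b + beta[t] * prev_a + k * beta[t] * prev_b
      prev_a <- abar[t]; prev_b <- bbar[t]
    }
    list(K = k, alpha = alpha, beta = beta, gamma = gamma,
         abar = abar, bbar = bbar, gbar = 1 - abar - k * bbar)
  })
  structure(list(T = as.integer(T_steps), kind = kind,
                 mask_fraction_final = mask_fraction_final,
                 uniform_weight = uniform_weight, channels = channels),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat("noise_schedule:", x$kind, "T =", x$T,
      "mask_fraction_final =", x$mask_fraction_final,
      "uniform_weight =", x$uniform_weight, "\n")
  cat("  channels:", paste(sprintf("%s(K=%d)", names(x$channels),
                                   vapply(x$channels, `[[`, 1L, "K")),
                           collapse = " "), "\n")
  invisible(x)
}

schedule_channel <- function(schedule, channel) {
  ch <- schedule$channels[[channel]]
  if (is.null(ch)) stop("schedule has no channel '", channel, "'")
  ch
}

mask_replace_matrix <- function(k, alpha, beta, gamma) {
  q <- matrix(0, k + 1, k + 1)
  q[seq_len(k), seq_len(k)] <- beta
  diag(q)[seq_len(k)] <- alpha + beta
  q[k + 1, seq_len(k)] <- gamma
  q[k + 1, k + 1] <- 1
  q
}

#' Per-step transition matrix Q_t
#'
#' @param t timestep in `1..T`.
#' @param channel channel name present in the schedule (`"A"`, `"C"`, `"E"`).
#' @param schedule a `noise_schedule`.
#' @return column-stochastic `(K+1) x (K+1)` matrix with an absorbing mask
#'   column.
#' @export
transition_matrix <- function(t, channel, schedule) {
  if (t < 1 || t > schedule$T) stop("t out of range [1, ", schedule$T, "]")
  ch <- schedule_channel(schedule, channel)
  mask_replace_matrix(ch$K, ch$alpha[t], ch$beta[t], ch$gamma[t])
}

#' Cumulative transition matrix Q-bar_t = Q_t ... Q_1
#'
#' Uses the closed-form recursion over (keep, uniform, mask) masses, which
#' agrees with the explicit matrix product to machine precision.
#'
#' @param t timestep in `0..T` (identity at 0).
#' @inheritParams transition_matrix
#' @return column-stochastic `(K+1) x (K+1)` matrix.
#' @export
cumulative_matrix <- function(t, channel, schedule) {
  if (t < 0 || t > schedule$T) stop("t out of range [0, ", schedule$T, "]")
  ch <- schedule_channel(schedule, channel)
  if (t == 0) return(diag(ch$K + 1))
  mask_replace_matrix(ch$K, ch$abar[t], ch$bbar[t], ch$gbar[t])
}

# cumulative (keep, uniform-per-category, mask) masses at t, allowing t = 0
cumulative_masses <- function(t, ch) {
  if (t == 0) c(a = 1, b = 0, g = 0)
  else c(a = ch$abar[t], b = ch$bbar[t], g = ch$gbar[t])
}
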