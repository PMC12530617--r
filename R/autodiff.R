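# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The denoiser's forward pass is written once against these ops. With no tape
# active and plain-matrix inputs every op falls through to ordinary matrix
# arithmetic (the cheap path used for sampling); during training parameters
# are wrapped as leaf nodes, a tape records every op, and ad_backward()
# replays it in reverse. Scalars are 1x1 matrices.

# The tape is an intrusive linked list: each node keeps a reference to the
# node created before it, so appending is O(1) and backward() simply walks
# the chain from the loss to the leaves.
.ad <- new.env(parent = emptyenv())
.ad$last <- NULL
.ad$active <- FALSE

# nodes are the only environments that flow through the ops, so the
# environment check doubles as a fast class test
is_node <- function(x) is.environment(x)
ad_value <- function(x) if (is.environment(x)) x$val else x

new_node <- function(val, backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$backfn <- backfn
  class(e) <- "adnode"
  if (.ad$active) {
    e$prev <- .ad$last
    .ad$last <- e
  }
  e
}

acc_grad <- function(x, g) {
  if (!is_node(x)) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

#' @noRd
ad_tape_start <- function() {
  .ad$active <- TRUE
  .ad$last <- NULL
  invisible(NULL)
}

ad_tape_stop <- function() {
  .ad$active <- FALSE
  .ad$last <- NULL
  invisible(NULL)
}

ad_param <- function(val) new_node(val)

ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$val) == 1)
  loss$grad <- matrix(1, 1, 1)
  e <- .ad$last
  while (!is.null(e)) {
    if (!is.null(e$backfn) && !is.null(e$grad)) e$backfn(e$grad)
    e <- e$prev
  }
  invisible(NULL)
}

# ops ----------------------------------------------------------------------

ad_mm <- function(a, b) {
  val <- ad_value(a) %*% ad_value(b)
  if (!is_node(a) && !is_node(b)) return(val)
  av <- ad_value(a); bv <- ad_value(b)
  new_node(val, function(g) {
    acc_grad(a, g %*% t(bv))
    acc_grad(b, t(av) %*% g)
  })
}

# b may be a same-shape matrix or a length-ncol(a) vector broadcast over rows
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  broadcast <- !is.matrix(bv) || (nrow(bv) == 1 && nrow(av) > 1)
  val <- if (broadcast) sweep(av, 2, as.numeric(bv), "+") else av + bv
  if (!is_node(a) && !is_node(b)) return(val)
  new_node(val, function(g) {
    acc_grad(a, g)
    acc_grad(b, if (broadcast) matrix(colSums(g), 1) else g)
  })
}

ad_hadamard <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  val <- av * bv
  if (!is_node(a) && !is_node(b)) return(val)
  new_node(val, function(g) {
    acc_grad(a, g * bv)
    acc_grad(b, g * av)
  })
}

ad_scale <- function(a, s) {
  val <- ad_value(a) * s
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, g * s))
}

ad_relu <- function(a) {
  av <- ad_value(a)
  val <- pmax(av, 0)
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, g * (av > 0)))
}

ad_tanh <- function(a) {
  val <- tanh(ad_value(a))
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, g * (1 - val^2)))
}

ad_softmax_rows <- function(a) {
  av <- ad_value(a)
  rowmax <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  z <- exp(av - rowmax)
  val <- z / rowSums(z)
  if (!is_node(a)) return(val)
  new_node(val, function(g) {
    acc_grad(a, val * (g - rowSums(g * val)))
  })
}

# numerically floored log (absorbing-state posteriors contain exact zeros)
ad_log <- function(a, floor = 1e-30) {
  av <- pmax(ad_value(a), floor)
  val <- log(av)
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, g / av))
}

ad_layernorm_rows <- function(a, gain, bias, eps = 1e-5) {
  av <- ad_value(a)
  mu <- rowMeans(av)
  xc <- av - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  gv <- as.numeric(ad_value(gain)); bv <- as.numeric(ad_value(bias))
  val <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  if (!is_node(a) && !is_node(gain) && !is_node(bias)) return(val)
  new_node(val, function(g) {
    acc_grad(gain, matrix(colSums(g * xhat), 1))
    acc_grad(bias, matrix(colSums(g), 1))
    gx <- sweep(g, 2, gv, "*")
    acc_grad(a, (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)) / sd_)
  })
}

ad_cbind <- function(args) {
  vals <- lapply(args, ad_value)
  val <- do.call(cbind, vals)
  if (!any(vapply(args, is_node, logical(1)))) return(val)
  widths <- vapply(vals, ncol, integer(1))
  stops <- cumsum(widths)
  starts <- stops - widths + 1L
  new_node(val, function(g) {
    for (k in seq_along(args)) {
      if (is_node(args[[k]])) {
        acc_grad(args[[k]], g[, starts[k]:stops[k], drop = FALSE])
      }
    }
  })
}

ad_gather_rows <- function(a, idx) {
  av <- ad_value(a)
  val <- av[idx, , drop = FALSE]
  if (!is_node(a)) return(val)
  nr <- nrow(av)
  new_node(val, function(g) {
    gs <- rowsum(g, group = idx)
    full <- matrix(0, nr, ncol(g))
    full[as.integer(rownames(gs)), ] <- gs
    acc_grad(a, full)
  })
}

# sum rows of `a` by group id (groups must cover 1..ngroups); the adjoint
# broadcasts the group gradient back to its member rows
ad_rowsum_groups <- function(a, groups, ngroups) {
  av <- ad_value(a)
  gs <- rowsum(av, group = groups)
  val <- matrix(0, ngroups, ncol(av))
  val[as.integer(rownames(gs)), ] <- gs
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, g[groups, , drop = FALSE]))
}

ad_t <- function(a) {
  val <- t(ad_value(a))
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, t(g)))
}

# scatter a column vector of values into a fixed template matrix at linear
# positions `pos` (every position is written exactly once); used to build
# block-diagonal attention biases where the template carries -Inf outside
# the blocks
ad_scatter_positions <- function(a, pos, template) {
  av <- ad_value(a)
  val <- template
  val[pos] <- av
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, matrix(g[pos], ncol = 1)))
}

ad_slice_cols <- function(a, cols) {
  av <- ad_value(a)
  val <- av[, cols, drop = FALSE]
  if (!is_node(a)) return(val)
  nc <- ncol(av)
  new_node(val, function(g) {
    full <- matrix(0, nrow(g), nc)
    full[, cols] <- g
    acc_grad(a, full)
  })
}

# column-major reshape (matrix() semantics)
ad_reshape <- function(a, nr, nc) {
  av <- ad_value(a)
  val <- matrix(av, nr, nc)
  if (!is_node(a)) return(val)
  d <- dim(av)
  new_node(val, function(g) acc_grad(a, matrix(g, d[1], d[2])))
}

ad_rbind <- function(args) {
  vals <- lapply(args, ad_value)
  val <- do.call(rbind, vals)
  if (!any(vapply(args, is_node, logical(1)))) return(val)
  heights <- vapply(vals, nrow, integer(1))
  stops <- cumsum(heights)
  starts <- stops - heights + 1L
  new_node(val, function(g) {
    for (k in seq_along(args)) {
      if (is_node(args[[k]])) {
        acc_grad(args[[k]], g[starts[k]:stops[k], , drop = FALSE])
      }
    }
  })
}

# scalar result: sum(a * w) for a constant weight matrix w
ad_sum_weighted <- function(a, w) {
  val <- matrix(sum(ad_value(a) * w), 1, 1)
  if (!is_node(a)) return(val)
  new_node(val, function(g) acc_grad(a, as.numeric(g) * w))
}

# weighted sum of scalar nodes/values -> scalar
ad_scalar_combine <- function(terms, weights) {
  val <- matrix(sum(vapply(terms, function(x) as.numeric(ad_value(x)),
                           numeric(1)) * weights), 1, 1)
  if (!any(vapply(terms, is_node, logical(1)))) return(val)
  new_node(val, function(g) {
    for (k in seq_along(terms)) {
      acc_grad(terms[[k]], matrix(as.numeric(g) * weights[k], 1, 1))
    }
  })
}
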