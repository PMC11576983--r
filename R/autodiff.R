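# Reverse-mode differentiation tape.
#
# Every tracked quantity is a base-R matrix wrapped in an environment node.
# Operations push nodes onto a tape in execution order; ad_backward() walks
# the tape in reverse and calls each node's backward closure, which
# accumulates gradients into the parents. Creation order is a topological
# order, so no explicit sort is needed.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 128L)
  t$n <- 0L
  t
}

.ad_push <- function(tape, nd) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

.ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  .ad_push(tape, nd)
}

.acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @noRd
ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  .ad_node(tape, x)
}

# Parameters are constants whose grads we read after the backward pass.
ad_param <- ad_const

ad_value <- function(nd) nd$value

ad_grad <- function(nd) {
  if (is.null(nd$grad)) matrix(0, nrow(nd$value), ncol(nd$value)) else nd$grad
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- elementwise and linear ops ------------------------------------------

ad_mm <- function(tape, a, b) {
  v <- a$value %*% b$value
  .ad_node(tape, v, function(g) {
    .acc(a, tcrossprod(g, b$value))
    .acc(b, crossprod(a$value, g))
  })
}

ad_t <- function(tape, a) {
  .ad_node(tape, t(a$value), function(g) .acc(a, t(g)))
}

# b may match a, be a 1 x k row (bias broadcast over rows), or be 1 x 1.
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    .ad_node(tape, av + bv, function(g) { .acc(a, g); .acc(b, g) })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    .ad_node(tape, av + bv[rep.int(1L, nrow(av)), , drop = FALSE], function(g) {
      .acc(a, g)
      .acc(b, matrix(.colSums(g, nrow(g), ncol(g)), 1L))
    })
  } else if (length(bv) == 1L) {
    .ad_node(tape, av + bv[1L], function(g) {
      .acc(a, g)
      .acc(b, matrix(sum(g), 1L, 1L))
    })
  } else stop("ad_add: incompatible shapes")
}

ad_sub <- function(tape, a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)) || length(b$value) == 1L)
  if (length(b$value) == 1L && length(a$value) != 1L) {
    .ad_node(tape, a$value - b$value[1L], function(g) {
      .acc(a, g); .acc(b, matrix(-sum(g), 1L, 1L))
    })
  } else {
    .ad_node(tape, a$value - b$value, function(g) {
      .acc(a, g); .acc(b, -g)
    })
  }
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    .ad_node(tape, av * bv, function(g) {
      .acc(a, g * bv)
      .acc(b, g * av)
    })
  } else if (length(bv) == 1L) {
    .ad_node(tape, av * bv[1L], function(g) {
      .acc(a, g * bv[1L])
      .acc(b, matrix(sum(g * av), 1L, 1L))
    })
  } else if (length(av) == 1L) {
    ad_mul(tape, b, a)
  } else stop("ad_mul: incompatible shapes")
}

ad_scale <- function(tape, a, k) {
  .ad_node(tape, a$value * k, function(g) .acc(a, g * k))
}

ad_addc <- function(tape, a, k) {
  .ad_node(tape, a$value + k, function(g) .acc(a, g))
}

ad_relu <- function(tape, a) {
  v <- a$value
  m <- v > 0
  .ad_node(tape, v * m, function(g) .acc(a, g * m))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  .ad_node(tape, s, function(g) .acc(a, g * s * (1 - s)))
}

ad_exp <- function(tape, a) {
  e <- exp(a$value)
  .ad_node(tape, e, function(g) .acc(a, g * e))
}

ad_log <- function(tape, a) {
  v <- a$value
  .ad_node(tape, log(v), function(g) .acc(a, g / v))
}

## ---- shape ops ------------------------------------------------------------

ad_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  .ad_node(tape, a$value[idx, , drop = FALSE], function(g) {
    G <- matrix(0, nrow(a$value), ncol(a$value))
    gr <- rowsum(g, group = idx)
    G[as.integer(rownames(gr)), ] <- gr
    .acc(a, G)
  })
}

ad_cbind <- function(tape, a, b) {
  ka <- ncol(a$value)
  .ad_node(tape, cbind(a$value, b$value), function(g) {
    .acc(a, g[, seq_len(ka), drop = FALSE])
    .acc(b, g[, -seq_len(ka), drop = FALSE])
  })
}

ad_rowsums <- function(tape, a) {
  k <- ncol(a$value)
  .ad_node(tape, matrix(.rowSums(a$value, nrow(a$value), k), ncol = 1L),
           function(g) {
    .acc(a, g[, rep(1L, k), drop = FALSE])
  })
}

ad_mean_all <- function(tape, a) {
  n <- length(a$value)
  .ad_node(tape, matrix(mean(a$value), 1L, 1L), function(g) {
    .acc(a, matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

ad_sum_all <- function(tape, a) {
  .ad_node(tape, matrix(sum(a$value), 1L, 1L), function(g) {
    .acc(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

# Mean of member-node rows per graph; index has values 1..ngroups, all present.
ad_group_mean <- function(tape, a, index, ngroups) {
  # rowsum is grouped C code; division by counts broadcasts per row
  index <- as.integer(index)
  cnt <- tabulate(index, nbins = ngroups)
  v <- rowsum(a$value, group = index) / cnt
  dimnames(v) <- NULL
  .ad_node(tape, v, function(g) {
    .acc(a, g[index, , drop = FALSE] / cnt[index])
  })
}

# Row-wise L2 normalization with an epsilon guard (cosine-similarity prep).
ad_row_l2_normalize <- function(tape, a, eps = 1e-12) {
  v <- a$value
  n <- nrow(v); k <- ncol(v)
  r <- sqrt(.rowSums(v * v, n, k) + eps)
  y <- v / r
  .ad_node(tape, y, function(g) {
    dot <- .rowSums(g * y, n, k)
    .acc(a, (g - y * dot) / r)
  })
}

# Column-vector broadcast multiply: a (n x k) * c (n x 1).
ad_mul_colvec <- function(tape, a, c) {
  av <- a$value; cv <- c$value[, 1L]
  .ad_node(tape, av * cv, function(g) {
    .acc(a, g * cv)
    .acc(c, matrix(rowSums(g * av), ncol = 1L))
  })
}

## ---- reductions for losses -------------------------------------------------

# log(mean(exp(a))) for an n x 1 column, max-shifted for stability.
ad_logmeanexp <- function(tape, a) {
  v <- a$value
  m <- max(v)
  e <- exp(v - m)
  s <- sum(e)
  .ad_node(tape, matrix(log(s / length(v)) + m, 1L, 1L), function(g) {
    .acc(a, g[1L] * e / s)
  })
}

.softmax_rows <- function(x) {
  n <- nrow(x)
  x <- x - x[cbind(seq_len(n), max.col(x, ties.method = "first"))]
  e <- exp(x)
  e / .rowSums(e, n, ncol(e))
}

# Mean cross-entropy of logits against integer labels in 1..C.
ad_softmax_ce <- function(tape, logits, labels) {
  labels <- as.integer(labels)
  P <- .softmax_rows(logits$value)
  n <- nrow(P)
  idx <- cbind(seq_len(n), labels)
  v <- matrix(-mean(log(pmax(P[idx], 1e-12))), 1L, 1L)
  .ad_node(tape, v, function(g) {
    D <- P
    D[idx] <- D[idx] - 1
    .acc(logits, g[1L] * D / n)
  })
}

# Mean cross-entropy against fixed soft targets (rows sum to one).
ad_softmax_ce_soft <- function(tape, logits, targets) {
  P <- .softmax_rows(logits$value)
  n <- nrow(P)
  v <- matrix(-mean(.rowSums(targets * log(pmax(P, 1e-12)), n, ncol(P))),
              1L, 1L)
  .ad_node(tape, v, function(g) {
    .acc(logits, g[1L] * (P - targets) / n)
  })
}

## ---- masked normalized propagation -----------------------------------------

# out = D^{-1/2} (A_m + I) D^{-1/2} %*% H where A_m carries mask weight m_e on
# both directions of each undirected edge and degrees are computed from the
# weighted A_m + I. Gradients flow into both the mask and H, including the
# path through the degrees.
ad_masked_norm_prop <- function(tape, mask, h, eu, ev, n) {
  E <- length(eu)
  m <- if (is.null(mask)) NULL else mask$value[, 1L]
  pat <- .norm_adj_pattern(eu, ev, n, m)
  H <- h$value
  v <- .norm_prop_apply(pat, H)
  .ad_node(tape, v, function(g) {
    .acc(h, .norm_prop_apply(pat, g))  # the operator is symmetric
    if (!is.null(mask) && E > 0L) {
      i <- pat$i; j <- pat$j; s <- pat$s; d <- pat$d; invsq <- pat$invsq
      Gi <- g[i, , drop = FALSE] * H[j, , drop = FALSE]
      Gpat <- .rowSums(Gi, nrow(Gi), ncol(Gi))
      gs <- Gpat * s
      t1 <- rep(0, n); t2 <- rep(0, n)
      a1 <- rowsum(matrix(gs, ncol = 1L), group = i)
      t1[as.integer(rownames(a1))] <- a1[, 1L]
      a2 <- rowsum(matrix(gs, ncol = 1L), group = j)
      t2[as.integer(rownames(a2))] <- a2[, 1L]
      dd <- -(t1 + t2) / (2 * d)
      idxe <- seq_len(E)
      dm <- Gpat[idxe] * invsq[idxe] +
        Gpat[E + idxe] * invsq[E + idxe] +
        dd[eu] + dd[ev]
      .acc(mask, matrix(dm, ncol = 1L))
    }
  })
}

## ---- parameter plumbing ----------------------------------------------------

# Wrap a flat named list of matrices as tape nodes.
ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# Collect gradients from wrapped parameter nodes (zeros where untouched).
ad_collect_grads <- function(pnodes) {
  lapply(pnodes, ad_grad)
}

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    k <- length(template[[nm]])
    out[[nm]] <- matrix(theta[pos + seq_len(k)],
                        nrow(template[[nm]]), ncol(template[[nm]]))
    pos <- pos + k
  }
  stopifnot(pos == length(theta))
  out
}
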