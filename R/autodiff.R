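# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor in the network stack is a plain R matrix wrapped in an
# environment ("node") carrying its value, an accumulated gradient, its
# parent nodes and an operation code.  Nodes are created in evaluation
# order, so reverse creation order is a valid topological order for the
# backward sweep.  Backward rules live in a single dispatch function
# (compiled once) rather than per-node closures, which keeps the
# interpreter overhead of building thousands of nodes per minibatch low.
# Every rule is validated against central finite differences in the
# test suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L
.ad_env$token <- 0L
.ad_env$idx_cache <- new.env(parent = emptyenv())

# Convolution/pooling index maps depend only on the geometry, so they
# are computed once per (shape, kernel, dilation) and reused.
.ad_cached <- function(key, build) {
  v <- .ad_env$idx_cache[[key]]
  if (is.null(v)) {
    v <- build()
    .ad_env$idx_cache[[key]] <- v
  }
  v
}

ad_node <- function(val, parents = NULL, op = NULL) {
  # force the promises BEFORE taking an id: nested op calls may create
  # parent nodes while `val` evaluates, and reverse id order must remain
  # a topological order of the graph
  force(parents)
  force(val)
  e <- new.env(parent = emptyenv())
  .ad_env$counter <- .ad_env$counter + 1L
  e$id <- .ad_env$counter
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$op <- op
  e$tok <- 0L
  class(e) <- "ad_node"
  e
}

#' @keywords internal
ad_const <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(x)
}

ad_param <- ad_const

is_ad_node <- function(x) inherits(x, "ad_node")

ad_value <- function(x) x$val

# Accumulate gradient g (same shape as node value) into node n.
ad_accum <- function(n, g) {
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

# Backward rule dispatch: applies the vector-Jacobian product of node n
# (with upstream gradient g) to its parents.
.ad_backstep <- function(n, g) {
  p <- n$parents
  switch(n$op,
    matmul = {
      ad_accum(p[[1]], g %*% t(p[[2]]$val))
      ad_accum(p[[2]], t(p[[1]]$val) %*% g)
    },
    add = {
      ad_accum(p[[1]], g)
      ad_accum(p[[2]], g)
    },
    sub = {
      ad_accum(p[[1]], g)
      ad_accum(p[[2]], -g)
    },
    add_bias = {
      ad_accum(p[[1]], g)
      ad_accum(p[[2]], matrix(colSums(g), 1L))
    },
    mul = {
      ad_accum(p[[1]], g * p[[2]]$val)
      ad_accum(p[[2]], g * p[[1]]$val)
    },
    scale = ad_accum(p[[1]], g * n$s),
    mul_rowvec = {
      vv <- as.vector(p[[2]]$val)
      ad_accum(p[[1]], sweep(g, 2L, vv, "*"))
      ad_accum(p[[2]], matrix(colSums(g * p[[1]]$val), 1L))
    },
    relu = ad_accum(p[[1]], g * (n$val > 0)),
    sigmoid = ad_accum(p[[1]], g * n$val * (1 - n$val)),
    tanh = ad_accum(p[[1]], g * (1 - n$val^2)),
    softmax = {
      s <- n$val
      ad_accum(p[[1]], (g - rowSums(g * s)) * s)
    },
    layernorm = {
      gg <- sweep(g, 2L, n$gv, "*")
      ad_accum(p[[1]], (gg - rowMeans(gg) - n$xhat * rowMeans(gg * n$xhat)) * n$inv)
      ad_accum(p[[2]], matrix(colSums(g * n$xhat), 1L))
      ad_accum(p[[3]], matrix(colSums(g), 1L))
    },
    mean_rows = {
      nr <- nrow(p[[1]]$val)
      ad_accum(p[[1]], matrix(as.vector(g), nr, ncol(p[[1]]$val),
                              byrow = TRUE) / nr)
    },
    concat_cols = {
      na <- ncol(p[[1]]$val)
      ad_accum(p[[1]], g[, seq_len(na), drop = FALSE])
      ad_accum(p[[2]], g[, -seq_len(na), drop = FALSE])
    },
    concat_rows = {
      na <- nrow(p[[1]]$val)
      ad_accum(p[[1]], g[seq_len(na), , drop = FALSE])
      ad_accum(p[[2]], g[-seq_len(na), , drop = FALSE])
    },
    slice_cols = {
      gx <- matrix(0, nrow(p[[1]]$val), ncol(p[[1]]$val))
      gx[, n$idx] <- g
      ad_accum(p[[1]], gx)
    },
    slice_row1 = {
      gx <- matrix(0, nrow(p[[1]]$val), ncol(p[[1]]$val))
      gx[1L, ] <- g
      ad_accum(p[[1]], gx)
    },
    reshape = ad_accum(p[[1]], matrix(as.vector(g), nrow(p[[1]]$val),
                                      ncol(p[[1]]$val))),
    transpose = ad_accum(p[[1]], t(g)),
    pool_rows = ad_accum(p[[1]], g[n$grp, , drop = FALSE] / n$p_fac),
    pool2d = ad_accum(p[[1]], g[n$grp, , drop = FALSE] / 4),
    broadcast_cols = ad_accum(p[[1]], matrix(sum(g), 1L, 1L)),
    conv1d = {
      xv <- p[[1]]$val; wv <- p[[2]]$val
      cin <- ncol(xv)
      gx <- matrix(0, nrow(xv), cin)
      gw <- matrix(0, nrow(wv), ncol(wv))
      for (j in seq_len(n$k)) {
        rows <- ((j - 1L) * cin + 1L):(j * cin)
        rot <- n$rots[[j]]
        gx[rot, ] <- gx[rot, , drop = FALSE] + g %*% t(wv[rows, , drop = FALSE])
        gw[rows, ] <- crossprod(xv[rot, , drop = FALSE], g)
      }
      ad_accum(p[[1]], gx)
      ad_accum(p[[2]], gw)
      ad_accum(p[[3]], matrix(colSums(g), 1L))
    },
    conv2d = {
      xv <- p[[1]]$val; wv <- p[[2]]$val
      cin <- ncol(xv)
      gx <- matrix(0, nrow(xv), cin)
      gw <- matrix(0, nrow(wv), ncol(wv))
      for (j in seq_along(n$taps)) {
        idx <- n$taps[[j]]
        ok <- n$tap_ok[[j]]
        rows <- ((j - 1L) * cin + 1L):(j * cin)
        gpart <- g %*% t(wv[rows, , drop = FALSE])
        gx_add <- rowsum(gpart[ok, , drop = FALSE], idx[ok], reorder = FALSE)
        tgt <- as.integer(rownames(gx_add))
        gx[tgt, ] <- gx[tgt, , drop = FALSE] + gx_add
        gw[rows, ] <- crossprod(n$xs[[j]], g)
      }
      ad_accum(p[[1]], gx)
      ad_accum(p[[2]], gw)
      ad_accum(p[[3]], matrix(colSums(g), 1L))
    },
    cross_entropy = {
      gz <- n$p_soft
      b <- nrow(gz)
      gz[cbind(seq_len(b), n$labels)] <- gz[cbind(seq_len(b), n$labels)] - 1
      ad_accum(p[[1]], gz * as.numeric(g) / b)
    },
    rlang::abort(paste0("no backward rule for op ", n$op))
  )
  invisible(NULL)
}

# Reverse sweep from a scalar (1x1) loss node.
ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$val) == 1L)
  .ad_env$token <- .ad_env$token + 1L
  tok <- .ad_env$token
  stack <- vector("list", 512L)
  stack[[1L]] <- loss
  sp <- 1L
  nodes <- vector("list", 1024L)
  k <- 0L
  while (sp > 0L) {
    n <- stack[[sp]]
    sp <- sp - 1L
    if (n$tok != tok) {
      n$tok <- tok
      k <- k + 1L
      if (k > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
      nodes[[k]] <- n
      for (pp in n$parents) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- pp
      }
    }
  }
  nodes <- nodes[seq_len(k)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1, 1)
  for (n in nodes[ord]) {
    if (!is.null(n$op) && !is.null(n$grad)) .ad_backstep(n, n$grad)
  }
  invisible(NULL)
}

## ---- primitive operations ---------------------------------------------
## All ops take ad_node arguments (wrap constants with ad_const()).

ad_matmul <- function(a, b) ad_node(a$val %*% b$val, list(a, b), "matmul")

ad_add <- function(a, b) ad_node(a$val + b$val, list(a, b), "add")

ad_sub <- function(a, b) ad_node(a$val - b$val, list(a, b), "sub")

# a: N x D matrix, bias: 1 x D row vector broadcast over rows
ad_add_bias <- function(a, bias) {
  ad_node(sweep(a$val, 2L, as.vector(bias$val), "+"), list(a, bias), "add_bias")
}

ad_mul <- function(a, b) ad_node(a$val * b$val, list(a, b), "mul")

ad_scale <- function(a, s) {
  out <- ad_node(a$val * s, list(a), "scale")
  out$s <- s
  out
}

# x: N x C, v: 1 x C channel gate broadcast over rows (SE gating)
ad_mul_rowvec <- function(x, v) {
  ad_node(sweep(x$val, 2L, as.vector(v$val), "*"), list(x, v), "mul_rowvec")
}

ad_relu <- function(a) ad_node(a$val * (a$val > 0), list(a), "relu")

ad_sigmoid <- function(a) ad_node(1 / (1 + exp(-a$val)), list(a), "sigmoid")

ad_tanh <- function(a) ad_node(tanh(a$val), list(a), "tanh")

# Row-wise softmax (used by scaled dot-product attention).
ad_softmax_rows <- function(a) {
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  ad_node(e / rowSums(e), list(a), "softmax")
}

# Row-wise layer normalization with learned gain/offset (1 x D each).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  xc <- xv - rowMeans(xv)
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$val)
  out <- ad_node(sweep(xhat, 2L, gv, "*") +
                   matrix(as.vector(beta$val), nrow(xv), ncol(xv), byrow = TRUE),
                 list(x, gamma, beta), "layernorm")
  out$inv <- inv; out$xhat <- xhat; out$gv <- gv
  out
}

# Mean over rows: N x D -> 1 x D (token pooling / global average pooling)
ad_mean_rows <- function(x) {
  ad_node(matrix(colMeans(x$val), 1L), list(x), "mean_rows")
}

ad_concat_cols <- function(a, b) {
  ad_node(cbind(a$val, b$val), list(a, b), "concat_cols")
}

ad_concat_rows <- function(a, b) {
  ad_node(rbind(a$val, b$val), list(a, b), "concat_rows")
}

ad_slice_cols <- function(x, idx) {
  out <- ad_node(x$val[, idx, drop = FALSE], list(x), "slice_cols")
  out$idx <- idx
  out
}

# first row of a node (CLS-token pooling)
ad_slice_rows_1 <- function(x) {
  ad_node(x$val[1L, , drop = FALSE], list(x), "slice_row1")
}

ad_reshape <- function(x, nrow, ncol) {
  ad_node(matrix(as.vector(x$val), nrow, ncol), list(x), "reshape")
}

ad_transpose <- function(x) ad_node(t(x$val), list(x), "transpose")

# Non-overlapping average pooling over rows: (p*T') x C -> T' x C
ad_pool_rows <- function(x, p) {
  n <- nrow(x$val)
  stopifnot(n %% p == 0L)
  grp <- .ad_cached(paste0("p1.", n, ".", p),
                    function() rep(seq_len(n %/% p), each = p))
  out <- ad_node(rowsum(x$val, grp, reorder = FALSE) / p, list(x), "pool_rows")
  out$grp <- grp; out$p_fac <- p
  out
}

# broadcast a 1x1 node across columns: 1 x d
ad_broadcast_cols <- function(s, d) {
  ad_node(matrix(s$val[1L, 1L], 1L, d), list(s), "broadcast_cols")
}

## ---- convolution / pooling on maps ------------------------------------

# 1-D convolution over time with circular padding.
# x: T x Cin, w: (k*Cin) x Cout (tap-major), b: 1 x Cout.
ad_conv1d <- function(x, w, b, k, dilation = 1L) {
  xv <- x$val; wv <- w$val
  tt <- nrow(xv); cin <- ncol(xv)
  stopifnot(nrow(wv) == k * cin)
  rots <- .ad_cached(paste0("c1.", tt, ".", k, ".", dilation), function() {
    offs <- dilation * (seq_len(k) - (k + 1L) %/% 2L)
    lapply(offs, function(o) ((seq_len(tt) - 1L + o) %% tt) + 1L)
  })
  y <- matrix(rep(as.vector(b$val), each = tt), tt)
  for (j in seq_len(k)) {
    wj <- wv[((j - 1L) * cin + 1L):(j * cin), , drop = FALSE]
    y <- y + xv[rots[[j]], , drop = FALSE] %*% wj
  }
  out <- ad_node(y, list(x, w, b), "conv1d")
  out$k <- k; out$rots <- rots
  out
}

# k x k 2-D convolution with zero "same" padding on a feature map stored
# as an (h*w) x C matrix, rows in column-major pixel order.
ad_conv2d <- function(x, w, b, h, wd, k = 3L, dilation = 1L) {
  xv <- x$val; wv <- w$val
  cin <- ncol(xv)
  stopifnot(nrow(xv) == h * wd, nrow(wv) == k * k * cin)
  geo <- .ad_cached(paste0("c2.", h, ".", wd, ".", k, ".", dilation), function() {
    half <- (k - 1L) %/% 2L
    ri <- rep(seq_len(h), times = wd)
    ci <- rep(seq_len(wd), each = h)
    taps <- list(); tap_ok <- list()
    t_id <- 0L
    for (dc in -half:half) for (dr in -half:half) {
      t_id <- t_id + 1L
      rr <- ri + dr * dilation
      cc <- ci + dc * dilation
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= wd
      taps[[t_id]] <- ifelse(ok, (cc - 1L) * h + rr, NA_integer_)
      tap_ok[[t_id]] <- ok
    }
    list(taps = taps, tap_ok = tap_ok)
  })
  taps <- geo$taps; tap_ok <- geo$tap_ok
  y <- matrix(rep(as.vector(b$val), each = h * wd), h * wd)
  xs <- vector("list", length(taps))
  for (j in seq_along(taps)) {
    idx <- taps[[j]]
    xi <- matrix(0, h * wd, cin)
    ok <- tap_ok[[j]]
    xi[ok, ] <- xv[idx[ok], , drop = FALSE]
    xs[[j]] <- xi
    wj <- wv[((j - 1L) * cin + 1L):(j * cin), , drop = FALSE]
    y <- y + xi %*% wj
  }
  out <- ad_node(y, list(x, w, b), "conv2d")
  out$taps <- taps; out$tap_ok <- tap_ok; out$xs <- xs
  out
}

# 2x2 average pooling with stride 2 on an (h*w) x C map (h, w even).
ad_pool2d <- function(x, h, wd) {
  stopifnot(h %% 2L == 0L, wd %% 2L == 0L)
  grp <- .ad_cached(paste0("p2.", h, ".", wd), function() {
    ri <- rep(seq_len(h), times = wd)
    ci <- rep(seq_len(wd), each = h)
    (ceiling(ci / 2) - 1L) * (h %/% 2L) + ceiling(ri / 2)
  })
  out <- ad_node(rowsum(x$val, grp, reorder = TRUE) / 4, list(x), "pool2d")
  out$grp <- grp
  out
}

# Mean softmax cross-entropy between logits (B x K) and integer labels
# in 1..K.  Returns a 1x1 loss node.
ad_cross_entropy <- function(logits, labels) {
  z <- logits$val
  b <- nrow(z)
  zmax <- apply(z, 1L, max)
  lse <- zmax + log(rowSums(exp(z - zmax)))
  picked <- z[cbind(seq_len(b), labels)]
  out <- ad_node(matrix(mean(lse - picked), 1L, 1L), list(logits),
                 "cross_entropy")
  out$p_soft <- exp(z - lse)
  out$labels <- labels
  out
}
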