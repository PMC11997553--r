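# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation on matrices and
# (n, nu, 3) vector-channel arrays. Each operation appends a node holding
# its value and a backward closure to a tape; ad_backward() replays the
# tape in reverse, accumulating gradients into leaf nodes. Correctness is
# pinned by finite-difference gradient checks in the test suite.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256)
  t$n <- 0L
  t
}

.ad_node <- function(tape, value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- node
  node
}

.acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_const <- function(tape, x) .ad_node(tape, x)

# leaf with gradient (model parameter)
ad_leaf <- function(tape, x) .ad_node(tape, x)

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$backward) && !is.null(node$grad))
      node$backward(node$grad)
  }
  invisible(NULL)
}

# --- scalar-channel (matrix) ops ------------------------------------------

ad_linear <- function(tape, x, W, b = NULL) {
  val <- x$value %*% W$value
  if (!is.null(b)) val <- sweep(val, 2, b$value, "+")
  .ad_node(tape, val, function(g) {
    .acc(x, g %*% t(W$value))
    .acc(W, t(x$value) %*% g)
    if (!is.null(b)) .acc(b, colSums(g))
  })
}

ad_add <- function(tape, a, b) {
  .ad_node(tape, a$value + b$value, function(g) {
    .acc(a, g); .acc(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  .ad_node(tape, a$value - b$value, function(g) {
    .acc(a, g); .acc(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  .ad_node(tape, a$value * b$value, function(g) {
    .acc(a, g * b$value); .acc(b, g * a$value)
  })
}

ad_smul <- function(tape, x, k) {
  .ad_node(tape, x$value * k, function(g) .acc(x, g * k))
}

ad_relu <- function(tape, x) {
  .ad_node(tape, pmax(x$value, 0), function(g) .acc(x, g * (x$value > 0)))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  .ad_node(tape, s, function(g) .acc(x, g * s * (1 - s)))
}

ad_concat <- function(tape, xs) {
  vals <- lapply(xs, `[[`, "value")
  widths <- vapply(vals, ncol, 1L)
  .ad_node(tape, do.call(cbind, vals), function(g) {
    off <- 0L
    for (j in seq_along(xs)) {
      .acc(xs[[j]], g[, off + seq_len(widths[j]), drop = FALSE])
      off <- off + widths[j]
    }
  })
}

ad_cols <- function(tape, x, idx) {
  .ad_node(tape, x$value[, idx, drop = FALSE], function(g) {
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[, idx] <- g
    .acc(x, gx)
  })
}

ad_rows <- function(tape, x, idx) {
  .ad_node(tape, x$value[idx, , drop = FALSE], function(g) {
    rs <- rowsum(g, group = idx)
    gx <- matrix(0, nrow(x$value), ncol(x$value))
    gx[as.integer(rownames(rs)), ] <- rs
    .acc(x, gx)
  })
}

# mean of rows of x grouped by idx, result has n rows (groups with no
# members get zero)
ad_scatter_mean <- function(tape, x, idx, n) {
  cnt <- tabulate(idx, nbins = n)
  rs <- rowsum(x$value, group = idx)
  val <- matrix(0, n, ncol(x$value))
  gi <- as.integer(rownames(rs))
  val[gi, ] <- rs / cnt[gi]
  .ad_node(tape, val, function(g) {
    .acc(x, g[idx, , drop = FALSE] / cnt[idx])
  })
}

ad_rowsum <- function(tape, x) {
  .ad_node(tape, matrix(rowSums(x$value), ncol = 1), function(g) {
    .acc(x, matrix(g, nrow(x$value), ncol(x$value)))
  })
}

ad_scale_cols <- function(tape, x, s) {
  # s: (n, 1); scales row i of x by s[i]
  v <- as.vector(s$value)
  .ad_node(tape, x$value * v, function(g) {
    .acc(x, g * v)
    .acc(s, matrix(rowSums(g * x$value), ncol = 1))
  })
}

ad_layernorm <- function(tape, x, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  .ad_node(tape, y, function(g) {
    .acc(x, inv * (g - rowMeans(g) - y * rowMeans(g * y)))
  })
}

# --- vector-channel ((n, nu, 3) array) ops --------------------------------

ad_vlinear <- function(tape, V, W) {
  # V: (n, nu_in, 3); W: (nu_in, nu_out)
  dv <- dim(V$value)
  val <- array(0, dim = c(dv[1], ncol(W$value), 3))
  for (k in 1:3)
    val[, , k] <- matrix(V$value[, , k], dv[1], dv[2]) %*% W$value
  .ad_node(tape, val, function(g) {
    gV <- array(0, dim = dv)
    gW <- matrix(0, nrow(W$value), ncol(W$value))
    for (k in 1:3) {
      gk <- matrix(g[, , k], dv[1], ncol(W$value))
      Vk <- matrix(V$value[, , k], dv[1], dv[2])
      gV[, , k] <- gk %*% t(W$value)
      gW <- gW + t(Vk) %*% gk
    }
    .acc(V, gV); .acc(W, gW)
  })
}

ad_vnorm <- function(tape, V, eps = 1e-8) {
  dv <- dim(V$value)
  sq <- matrix(V$value[, , 1]^2 + V$value[, , 2]^2 + V$value[, , 3]^2,
               dv[1], dv[2])
  N <- sqrt(sq + eps)
  .ad_node(tape, N, function(g) {
    gV <- array(0, dim = dv)
    for (k in 1:3)
      gV[, , k] <- g * matrix(V$value[, , k], dv[1], dv[2]) / N
    .acc(V, gV)
  })
}

ad_vgate <- function(tape, V, s) {
  # s: (n, nu) scalar gate per vector
  dv <- dim(V$value)
  val <- array(0, dim = dv)
  for (k in 1:3) val[, , k] <- matrix(V$value[, , k], dv[1], dv[2]) * s$value
  .ad_node(tape, val, function(g) {
    gV <- array(0, dim = dv)
    gs <- matrix(0, dv[1], dv[2])
    for (k in 1:3) {
      gk <- matrix(g[, , k], dv[1], dv[2])
      gV[, , k] <- gk * s$value
      gs <- gs + gk * matrix(V$value[, , k], dv[1], dv[2])
    }
    .acc(V, gV); .acc(s, gs)
  })
}

ad_vconcat <- function(tape, Vs) {
  dims <- lapply(Vs, function(v) dim(v$value))
  n <- dims[[1]][1]
  nus <- vapply(dims, `[`, 1L, 2L)
  val <- array(0, dim = c(n, sum(nus), 3))
  off <- 0L
  for (j in seq_along(Vs)) {
    val[, off + seq_len(nus[j]), ] <- Vs[[j]]$value
    off <- off + nus[j]
  }
  .ad_node(tape, val, function(g) {
    off <- 0L
    for (j in seq_along(Vs)) {
      .acc(Vs[[j]], g[, off + seq_len(nus[j]), , drop = FALSE])
      off <- off + nus[j]
    }
  })
}

ad_vrows <- function(tape, V, idx) {
  dv <- dim(V$value)
  .ad_node(tape, V$value[idx, , , drop = FALSE], function(g) {
    gV <- array(0, dim = dv)
    for (k in 1:3) {
      gk <- matrix(g[, , k], length(idx), dv[2])
      rs <- rowsum(gk, group = idx)
      gk2 <- matrix(0, dv[1], dv[2])
      gk2[as.integer(rownames(rs)), ] <- rs
      gV[, , k] <- gV[, , k] + gk2
    }
    .acc(V, gV)
  })
}

ad_vscatter_mean <- function(tape, V, idx, n) {
  dv <- dim(V$value)
  cnt <- tabulate(idx, nbins = n)
  val <- array(0, dim = c(n, dv[2], 3))
  for (k in 1:3) {
    rs <- rowsum(matrix(V$value[, , k], dv[1], dv[2]), group = idx)
    gi <- as.integer(rownames(rs))
    val[gi, , k] <- rs / cnt[gi]
  }
  .ad_node(tape, val, function(g) {
    gV <- array(0, dim = dv)
    for (k in 1:3)
      gV[, , k] <- matrix(g[, , k], n, dv[2])[idx, , drop = FALSE] / cnt[idx]
    .acc(V, gV)
  })
}

ad_vadd <- function(tape, a, b) {
  .ad_node(tape, a$value + b$value, function(g) {
    .acc(a, g); .acc(b, g)
  })
}

# row-wise RMS normalization of the vector channel:
# r_i = sqrt(mean_j ||v_ij||^2 + eps); out = V / r
ad_vrms <- function(tape, V, eps = 1e-8) {
  dv <- dim(V$value)
  nu <- dv[2]
  sq <- matrix(V$value[, , 1]^2 + V$value[, , 2]^2 + V$value[, , 3]^2,
               dv[1], nu)
  r <- sqrt(rowSums(sq) / nu + eps)
  val <- array(0, dim = dv)
  for (k in 1:3) val[, , k] <- matrix(V$value[, , k], dv[1], nu) / r
  .ad_node(tape, val, function(g) {
    tdot <- numeric(dv[1])
    for (k in 1:3)
      tdot <- tdot + rowSums(matrix(g[, , k], dv[1], nu) *
                               matrix(V$value[, , k], dv[1], nu))
    gV <- array(0, dim = dv)
    for (k in 1:3)
      gV[, , k] <- matrix(g[, , k], dv[1], nu) / r -
        matrix(V$value[, , k], dv[1], nu) * tdot / (nu * r^3)
    .acc(V, gV)
  })
}

# --- loss ------------------------------------------------------------------

# numerically stable mean binary cross-entropy on logits
ad_bce_logits <- function(tape, z, y) {
  zv <- as.vector(z$value)
  n <- length(zv)
  loss <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  .ad_node(tape, loss, function(g) {
    p <- 1 / (1 + exp(-zv))
    .acc(z, matrix(g * (p - y) / n, ncol = 1))
  })
}
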