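# Minimal tape-based reverse-mode autodiff over R arrays.
#
# A tensor node is an environment: $v value (numeric array / matrix / vector),
# $g accumulated gradient (NULL until backward), $bw backward closure,
# $requires whether gradients flow into it. Feature maps are (H, W, C)
# arrays; conv weights (kh, kw, Cin, Cout); linear weights (in, out).
# Nodes are appended to a tape in creation order, which is a valid
# topological order, so backward() is a single reverse sweep.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$nodes <- list()
.ag$n <- 0L

ag_begin <- function() {
  .ag$recording <- TRUE
  .ag$nodes <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_end <- function() {
  .ag$recording <- FALSE
  .ag$nodes <- list()
  .ag$n <- 0L
  invisible(NULL)
}

new_node <- function(v, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  req <- FALSE
  for (p in parents) if (p$requires) { req <- TRUE; break }
  e$requires <- req
  class(e) <- "ag"
  if (.ag$recording && req && !is.null(bw)) {
    e$parents <- parents
    e$bw <- bw
    n <- .ag$n + 1L
    if (n > length(.ag$nodes)) .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
    .ag$nodes[[n]] <- e
    .ag$n <- n
  }
  e
}

ag_const <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v; e$g <- NULL; e$requires <- FALSE
  class(e) <- "ag"
  e
}

ag_var <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v; e$g <- NULL; e$requires <- TRUE
  class(e) <- "ag"
  e
}

as_ag <- function(x) if (inherits(x, "ag")) x else ag_const(x)

acc_grad <- function(p, g) {
  if (!p$requires) return(invisible(NULL))
  if (is.null(p$g)) p$g <- g else p$g <- p$g + g
  invisible(NULL)
}

#' @keywords internal
backward <- function(loss) {
  loss$g <- array(1, dim = if (is.null(dim(loss$v))) length(loss$v) else dim(loss$v))
  if (.ag$n > 0L) {
    for (i in seq.int(.ag$n, 1L)) {
      nd <- .ag$nodes[[i]]
      if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd)
    }
  }
  invisible(NULL)
}

keep_dim <- function(g, v) {
  if (!is.null(dim(v))) dim(g) <- dim(v)
  g
}

# ---- elementwise ----------------------------------------------------------

ag_relu <- function(x) {
  m <- x$v > 0
  new_node(x$v * m, list(x), function(nd) acc_grad(x, keep_dim(nd$g * m, x$v)))
}

ag_lrelu <- function(x, slope = 0.2) {
  m <- ifelse(x$v > 0, 1, slope)
  new_node(x$v * m, list(x), function(nd) acc_grad(x, keep_dim(nd$g * m, x$v)))
}

ag_tanh <- function(x) {
  y <- tanh(x$v)
  new_node(y, list(x), function(nd) acc_grad(x, keep_dim(nd$g * (1 - y^2), x$v)))
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  new_node(y, list(x), function(nd) acc_grad(x, keep_dim(nd$g * y * (1 - y), x$v)))
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  new_node(a$v + b$v, list(a, b), function(nd) {
    acc_grad(a, keep_dim(nd$g, a$v)); acc_grad(b, keep_dim(nd$g, b$v))
  })
}

ag_affine <- function(x, mul = 1, add = 0) {
  new_node(x$v * mul + add, list(x),
           function(nd) acc_grad(x, keep_dim(nd$g * mul, x$v)))
}

# ---- conv / pooling / resampling -----------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- cpp_conv2d(x$v, w$v, as.numeric(b$v), as.integer(stride), as.integer(pad))
  new_node(y, list(x, w, b), function(nd) {
    r <- cpp_conv2d_bw(x$v, w$v, nd$g, as.integer(stride), as.integer(pad))
    acc_grad(x, r$gx); acc_grad(w, r$gw); acc_grad(b, as.numeric(r$gb))
  })
}

ag_maxpool2 <- function(x) {
  r <- cpp_maxpool2(x$v)
  new_node(r$y, list(x), function(nd) {
    gx <- array(0, dim = dim(x$v))
    idx <- as.vector(r$idx)
    gv <- as.vector(nd$g)
    # argmax ties impossible within a window only up to equal values; first wins
    gx_flat <- as.vector(gx)
    gadd <- tapply(gv, idx, sum)
    gx_flat[as.integer(names(gadd))] <- gadd
    dim(gx_flat) <- dim(x$v)
    acc_grad(x, gx_flat)
  })
}

ag_upsample2 <- function(x) {
  d <- dim(x$v)
  ri <- rep(seq_len(d[1]), each = 2L); ci <- rep(seq_len(d[2]), each = 2L)
  y <- x$v[ri, ci, , drop = FALSE]
  new_node(y, list(x), function(nd) {
    g <- nd$g
    g1 <- g[seq(1, 2 * d[1], 2), , , drop = FALSE] + g[seq(2, 2 * d[1], 2), , , drop = FALSE]
    gx <- g1[, seq(1, 2 * d[2], 2), , drop = FALSE] + g1[, seq(2, 2 * d[2], 2), , drop = FALSE]
    acc_grad(x, gx)
  })
}

ag_concat_c <- function(a, b) {
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(da[1] == db[1], da[2] == db[2])
  y <- array(c(a$v, b$v), dim = c(da[1], da[2], da[3] + db[3]))
  new_node(y, list(a, b), function(nd) {
    acc_grad(a, nd$g[, , seq_len(da[3]), drop = FALSE])
    acc_grad(b, nd$g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ag_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v); n <- d[1] * d[2]
  mu <- apply(x$v, 3, mean)
  va <- apply(x$v, 3, function(s) mean((s - mean(s))^2))
  sd_ <- sqrt(va + eps)
  xh <- sweep(sweep(x$v, 3, mu, "-"), 3, sd_, "/")
  y <- sweep(sweep(xh, 3, gamma$v, "*"), 3, beta$v, "+")
  new_node(y, list(x, gamma, beta), function(nd) {
    g <- nd$g
    dgamma <- apply(g * xh, 3, sum)
    dbeta <- apply(g, 3, sum)
    gm <- apply(g, 3, mean)
    gxm <- apply(g * xh, 3, mean)
    t1 <- sweep(g, 3, gm, "-")
    t2 <- sweep(xh, 3, gxm, "*")
    gx <- sweep(t1 - t2, 3, gamma$v / sd_, "*")
    acc_grad(x, gx); acc_grad(gamma, dgamma); acc_grad(beta, dbeta)
  })
}

# global average pool: (H,W,C) -> length-C vector
ag_gap <- function(x) {
  d <- dim(x$v); n <- d[1] * d[2]
  y <- apply(x$v, 3, mean)
  new_node(y, list(x), function(nd) {
    g <- array(rep(nd$g / n, each = n), dim = d)
    acc_grad(x, g)
  })
}

# channel mean: (H,W,C) -> (H,W,1); the RGB-to-gray step inside the graph
ag_chanmean <- function(x) {
  d <- dim(x$v)
  y <- array(apply(x$v, c(1, 2), mean), dim = c(d[1], d[2], 1L))
  new_node(y, list(x), function(nd) {
    g <- array(rep(as.vector(nd$g), d[3]) / d[3], dim = d)
    acc_grad(x, g)
  })
}

# ---- linear algebra -------------------------------------------------------

ag_linear <- function(x, w, b) {
  xm <- if (is.matrix(x$v)) x$v else matrix(x$v, nrow = 1)
  y <- xm %*% w$v
  y <- sweep(y, 2, as.numeric(b$v), "+")
  if (!is.matrix(x$v)) y <- as.numeric(y)
  new_node(y, list(x, w, b), function(nd) {
    gm <- if (is.matrix(nd$g)) nd$g else matrix(nd$g, nrow = 1)
    acc_grad(x, keep_dim(gm %*% t(w$v), x$v))
    acc_grad(w, t(xm) %*% gm)
    acc_grad(b, colSums(gm))
  })
}

ag_matmul <- function(a, b) {
  new_node(a$v %*% b$v, list(a, b), function(nd) {
    acc_grad(a, nd$g %*% t(b$v))
    acc_grad(b, t(a$v) %*% nd$g)
  })
}

# select rows of the (H*W, C) flattening of a (H,W,C) map
ag_gather_rows <- function(x, idx) {
  d <- dim(x$v)
  m <- matrix(x$v, nrow = d[1] * d[2], ncol = d[3])
  y <- m[idx, , drop = FALSE]
  new_node(y, list(x), function(nd) {
    gm <- matrix(0, d[1] * d[2], d[3])
    for (k in seq_along(idx)) gm[idx[k], ] <- gm[idx[k], ] + nd$g[k, ]
    dim(gm) <- d
    acc_grad(x, gm)
  })
}

ag_l2norm_rows <- function(x, eps = 1e-10) {
  nrm <- sqrt(rowSums(x$v^2)) + eps
  y <- x$v / nrm
  new_node(y, list(x), function(nd) {
    dot <- rowSums(nd$g * x$v)
    gx <- nd$g / nrm - x$v * (dot / nrm^3)
    acc_grad(x, gx)
  })
}

# mean over rows of softmax cross-entropy with integer targets (1-based)
ag_cross_entropy_rows <- function(logits, target) {
  lm <- logits$v
  mx <- apply(lm, 1, max)
  ex <- exp(lm - mx)
  sm <- ex / rowSums(ex)
  n <- nrow(lm)
  picked <- sm[cbind(seq_len(n), target)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  new_node(loss, list(logits), function(nd) {
    oh <- matrix(0, n, ncol(lm)); oh[cbind(seq_len(n), target)] <- 1
    acc_grad(logits, as.numeric(nd$g) * (sm - oh) / n)
  })
}

# ---- reductions / losses --------------------------------------------------

ag_mean <- function(x) {
  n <- length(x$v)
  new_node(mean(x$v), list(x), function(nd)
    acc_grad(x, keep_dim(array(as.numeric(nd$g) / n, dim = n), x$v)))
}

# mean((x - t)^2) against a constant target scalar or array
ag_sqmean <- function(x, t) {
  d <- x$v - t
  n <- length(d)
  new_node(mean(d^2), list(x), function(nd)
    acc_grad(x, keep_dim(as.numeric(nd$g) * 2 * d / n, x$v)))
}

# mean |a - b|, both may be tensors
ag_l1 <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  d <- a$v - b$v
  n <- length(d)
  s <- sign(d)
  new_node(mean(abs(d)), list(a, b), function(nd) {
    acc_grad(a, keep_dim(as.numeric(nd$g) * s / n, a$v))
    acc_grad(b, keep_dim(-as.numeric(nd$g) * s / n, b$v))
  })
}

# soft-threshold saliency as a differentiable node:
# m = 1 - sigmoid((v - threshold) * slope), v on the 0-255 scale
ag_saliency <- function(x, threshold, slope = 100) {
  z <- (x$v - threshold) * slope
  s <- 1 / (1 + exp(-z))
  new_node(1 - s, list(x), function(nd)
    acc_grad(x, keep_dim(-as.numeric(slope) * s * (1 - s) * nd$g, x$v)))
}

# ---- parameters and optimiser --------------------------------------------

# collect ag nodes from an arbitrarily nested list
params_of <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "ag")) out[[length(out) + 1L]] <<- e
    else if (is.list(e)) for (el in e) walk(el)
  }
  walk(x)
  out
}

adam_new <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = if (is.null(dim(p$v))) length(p$v) else dim(p$v)))
  st$v <- lapply(params, function(p) array(0, dim = if (is.null(dim(p$v))) length(p$v) else dim(p$v)))
  st
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$g)) next
    g <- p$g
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g^2
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$v <- p$v - lr * keep_dim(as.vector(mhat) / (sqrt(as.vector(vhat)) + eps), p$v)
  }
  for (p in params) p$g <- NULL
  invisible(NULL)
}

zero_grads <- function(params) { for (p in params) p$g <- NULL; invisible(NULL) }

# ---- (de)serialisation ----------------------------------------------------

# weights of a nested layer list as plain arrays, structure-preserving
net_state <- function(net) {
  if (inherits(net, "ag")) return(net$v)
  if (is.list(net)) return(lapply(net, net_state))
  net
}

net_load_state <- function(net, state) {
  if (inherits(net, "ag")) { net$v <- state; return(invisible(net)) }
  if (is.list(net)) for (i in seq_along(net)) net_load_state(net[[i]], state[[i]])
  invisible(net)
}
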