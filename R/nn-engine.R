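# Minimal CPU CNN engine.
#
# Tensors are numeric arrays with dim (H, W, C, N). A network is a list of
# nodes in topological order; each node names its input node(s) and carries
# its parameters. Forward caches per-node activations so backward can run in
# reverse order with hand-derived gradients. Heavy kernels (convolution,
# maxpool) live in src/nn_ops.cpp; everything else is vectorised R.

nn_graph <- function() {
  structure(list(nodes = list()), class = "nn_graph")
}

nn_add <- function(g, type, inputs = integer(), ...) {
  node <- c(list(type = type, inputs = as.integer(inputs)), list(...))
  g$nodes[[length(g$nodes) + 1L]] <- node
  g$last <- length(g$nodes)
  g
}

nn_conv <- function(g, from, cin, cout, k = 3L, stride = 1L, seed_rng = NULL) {
  sd <- sqrt(2 / (k * k * cin)) # He initialisation
  w <- array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
  nn_add(g, "conv", from, w = w, stride = as.integer(stride),
         pad = as.integer((k - 1L) / 2L))
}

nn_bn <- function(g, from, c) {
  nn_add(g, "bn", from,
         gamma = rep(1, c), beta = rep(0, c),
         run_mean = rep(0, c), run_var = rep(1, c), momentum = 0.9, eps = 1e-5)
}

nn_relu    <- function(g, from) nn_add(g, "relu", from)
nn_maxpool <- function(g, from) nn_add(g, "maxpool", from)
nn_gap     <- function(g, from) nn_add(g, "gap", from)
nn_addn    <- function(g, a, b) nn_add(g, "add", c(a, b))
nn_upsample <- function(g, from) nn_add(g, "upsample", from)
nn_concat  <- function(g, a, b) nn_add(g, "concat", c(a, b))

nn_dense <- function(g, from, cin, cout, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") matrix(0, cout, cin) else
    matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), nrow = cout)
  nn_add(g, "dense", from, w = w, b = rep(0, cout))
}

#' @noRd
nn_param_names <- function(node) {
  switch(node$type,
         conv = "w", bn = c("gamma", "beta"), dense = c("w", "b"),
         character(0))
}

# ---- forward ---------------------------------------------------------------

.up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

.down2_sum <- function(g) {
  d <- dim(g)
  h <- d[1] / 2; w <- d[2] / 2
  g1 <- g[seq(1, d[1], 2), , , , drop = FALSE] + g[seq(2, d[1], 2), , , , drop = FALSE]
  g1[, seq(1, d[2], 2), , , drop = FALSE] + g1[, seq(2, d[2], 2), , , drop = FALSE]
}

.bn_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])            # columns indexed by (c, n)
  cm <- matrix(colMeans(m), nrow = d[3])        # C x N
  mu <- rowMeans(cm) * 1                        # weight equal per sample
  cs <- matrix(colMeans(m^2), nrow = d[3])
  v <- rowMeans(cs) - mu^2
  list(mu = mu, var = pmax(v, 0))
}

.bcast_c <- function(v, d) {
  # replicate per-channel vector v over an (H, W, C, N) tensor
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

nn_forward <- function(net, x, train = FALSE, keep = integer()) {
  nodes <- net$nodes
  n <- length(nodes)
  acts <- vector("list", n)
  caches <- vector("list", n)
  # in inference mode, free each activation after its last consumer so large
  # slides/batches do not hold the whole graph in memory
  last_use <- integer(n)
  if (!train)
    for (j in seq_len(n))
      for (ip in nodes[[j]]$inputs) last_use[ip] <- j
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    a <- if (length(nd$inputs)) acts[[nd$inputs[1]]] else NULL
    out <- switch(nd$type,
      input = x,
      conv = cpp_conv2d_fw(a, nd$w, nd$stride, nd$pad),
      bn = {
        d <- dim(a)
        if (train) {
          st <- .bn_stats(a)
          nodes[[i]]$run_mean <- nd$momentum * nd$run_mean + (1 - nd$momentum) * st$mu
          nodes[[i]]$run_var  <- nd$momentum * nd$run_var  + (1 - nd$momentum) * st$var
        } else {
          st <- list(mu = nd$run_mean, var = nd$run_var)
        }
        inv <- 1 / sqrt(st$var + nd$eps)
        xhat <- (a - .bcast_c(st$mu, d)) * .bcast_c(inv, d)
        if (train) caches[[i]] <- list(xhat = xhat, inv = inv)
        xhat * .bcast_c(nd$gamma, d) + .bcast_c(nd$beta, d)
      },
      relu = { y <- a * (a > 0); if (train) caches[[i]] <- (a > 0); y },
      maxpool = {
        r <- cpp_maxpool2_fw(a)
        if (train) caches[[i]] <- list(arg = r$arg, xdim = dim(a))
        r$y
      },
      gap = {
        d <- dim(a)
        if (train) caches[[i]] <- d
        matrix(colMeans(matrix(a, nrow = d[1] * d[2])), nrow = d[3])
      },
      dense = nd$w %*% a + nd$b,
      add = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]],
      upsample = { if (train) caches[[i]] <- dim(a); .up2(a) },
      concat = {
        a2 <- acts[[nd$inputs[2]]]
        d1 <- dim(a); d2 <- dim(a2)
        y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        y[, , seq_len(d1[3]), ] <- a
        y[, , d1[3] + seq_len(d2[3]), ] <- a2
        if (train) caches[[i]] <- c(d1[3], d2[3])
        y
      },
      stop("unknown node type: ", nd$type))
    acts[[i]] <- out
    if (!train)
      for (ip in nd$inputs)
        if (last_use[ip] == i && !(ip %in% keep)) acts[ip] <- list(NULL)
  }
  net$nodes <- nodes # updated BN running stats
  list(net = net, acts = acts, caches = caches, out = acts[[n]])
}

# ---- backward --------------------------------------------------------------

nn_backward <- function(net, fw, gout) {
  nodes <- net$nodes
  n <- length(nodes)
  grads_out <- vector("list", n)  # gradient wrt each node's output
  pgrads <- vector("list", n)     # gradient wrt each node's parameters
  grads_out[[n]] <- gout
  for (i in rev(seq_len(n))) {
    g <- grads_out[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    push <- function(j, val) {
      grads_out[[j]] <<- if (is.null(grads_out[[j]])) val else grads_out[[j]] + val
    }
    switch(nd$type,
      input = NULL,
      conv = {
        r <- cpp_conv2d_bw(fw$acts[[nd$inputs[1]]], nd$w, g, nd$stride, nd$pad)
        pgrads[[i]] <- list(w = r$gw)
        push(nd$inputs[1], r$gx)
      },
      bn = {
        cc <- fw$caches[[i]]
        d <- dim(cc$xhat)
        npx <- d[1] * d[2] * d[4]
        gm <- matrix(g, nrow = d[1] * d[2])
        xm <- matrix(cc$xhat, nrow = d[1] * d[2])
        sum_g  <- rowSums(matrix(colSums(gm), nrow = d[3]))
        sum_gx <- rowSums(matrix(colSums(gm * xm), nrow = d[3]))
        pgrads[[i]] <- list(gamma = sum_gx, beta = sum_g)
        coef <- nd$gamma * cc$inv
        gx <- .bcast_c(coef, d) *
          (g - .bcast_c(sum_g / npx, d) - cc$xhat * .bcast_c(sum_gx / npx, d))
        push(nd$inputs[1], gx)
      },
      relu = push(nd$inputs[1], g * fw$caches[[i]]),
      maxpool = push(nd$inputs[1],
                     cpp_maxpool2_bw(g, fw$caches[[i]]$arg, fw$caches[[i]]$xdim)),
      gap = {
        d <- fw$caches[[i]]
        gx <- array(rep(as.numeric(g), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
        push(nd$inputs[1], gx)
      },
      dense = {
        a <- fw$acts[[nd$inputs[1]]]
        pgrads[[i]] <- list(w = g %*% t(a), b = rowSums(g))
        push(nd$inputs[1], t(nd$w) %*% g)
      },
      add = { push(nd$inputs[1], g); push(nd$inputs[2], g) },
      upsample = push(nd$inputs[1], .down2_sum(g)),
      concat = {
        cs <- fw$caches[[i]]
        push(nd$inputs[1], g[, , seq_len(cs[1]), , drop = FALSE])
        push(nd$inputs[2], g[, , cs[1] + seq_len(cs[2]), , drop = FALSE])
      },
      stop("unknown node type: ", nd$type))
  }
  pgrads
}

# ---- optimiser -------------------------------------------------------------

adam_state <- function(net) {
  lapply(net$nodes, function(nd) {
    nms <- nn_param_names(nd)
    if (!length(nms)) return(NULL)
    stats::setNames(lapply(nms, function(p) {
      list(m = nd[[p]] * 0, v = nd[[p]] * 0)
    }), nms)
  })
}

adam_step <- function(net, pgrads, state, t,
                      lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$nodes)) {
    st <- state[[i]]
    if (is.null(st) || is.null(pgrads[[i]])) next
    for (p in names(st)) {
      gp <- pgrads[[i]][[p]]
      st[[p]]$m <- beta1 * st[[p]]$m + (1 - beta1) * gp
      st[[p]]$v <- beta2 * st[[p]]$v + (1 - beta2) * gp^2
      mhat <- st[[p]]$m / (1 - beta1^t)
      vhat <- st[[p]]$v / (1 - beta2^t)
      net$nodes[[i]][[p]] <- net$nodes[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state[[i]] <- st
  }
  list(net = net, state = state)
}

# ---- losses ----------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable binary cross-entropy with logits; returns loss averaged
# over all elements and the gradient wrt the logits.
bce_with_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  grad <- (sigmoid(z) - y) / n
  dim(grad) <- dim(z)
  list(loss = loss, grad = grad)
}
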