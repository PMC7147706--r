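# Minimal static-graph CNN engine. A network is an ordered list of nodes
# (conv, convt, bn, relu, maxpool, concat, add, sigmoid) whose `inputs` refer
# to earlier node ids (0 = the network input). Parameters live in a named list;
# forward caches what the hand-derived backward passes need. All heavy kernels
# are C++ (im2col + BLAS GEMM).

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g
}

nn_add <- function(g, op, inputs, ...) {
  inputs <- as.integer(inputs)  # force before reading graph length: callers nest builder calls
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- c(list(op = op, inputs = inputs), list(...))
  id
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

nn_conv <- function(g, input, name, k, cin, cout, stride = 1L, pad = k %/% 2) {
  g$params[[name]] <- list(type = "conv", W = he_init(k, k, cin, cout),
                           b = numeric(cout))
  nn_add(g, "conv", input, param = name, stride = as.integer(stride),
         pad = as.integer(pad))
}

nn_convt <- function(g, input, name, cin, cout) {
  g$params[[name]] <- list(type = "conv", W = he_init(2, 2, cin, cout),
                           b = numeric(cout))
  nn_add(g, "convt", input, param = name)
}

nn_bn <- function(g, input, name, c) {
  g$params[[name]] <- list(type = "bn", gamma = rep(1, c), beta = numeric(c),
                           rmean = numeric(c), rvar = rep(1, c))
  nn_add(g, "bn", input, param = name)
}

nn_relu <- function(g, input) nn_add(g, "relu", input)

nn_maxpool <- function(g, input, k = 3L, stride = 2L, pad = 1L) {
  nn_add(g, "maxpool", input, k = as.integer(k), stride = as.integer(stride),
         pad = as.integer(pad))
}

# id of the last node that consumes each node's output (for freeing memory)
nn_last_use <- function(nodes) {
  n <- length(nodes)
  last <- integer(n)
  for (id in seq_len(n)) {
    for (i in nodes[[id]]$inputs) if (i > 0L) last[i] <- id
  }
  last[n] <- n + 1L  # network output survives
  last
}

nn_forward <- function(model, x, training = FALSE, keep = FALSE) {
  nodes <- model$nodes
  n <- length(nodes)
  acts <- vector("list", n)
  caches <- vector("list", n)
  bn_updates <- list()
  last <- if (!keep) nn_last_use(nodes)
  fetch <- function(i) if (i == 0L) x else acts[[i]]
  for (id in seq_len(n)) {
    nd <- nodes[[id]]
    a <- fetch(nd$inputs[1])
    y <- switch(nd$op,
      conv = {
        p <- model$params[[nd$param]]
        cpp_conv2d_fwd(a, p$W, p$b, nd$stride, nd$pad)
      },
      convt = {
        p <- model$params[[nd$param]]
        cpp_convt2_fwd(a, p$W, p$b)
      },
      bn = {
        p <- model$params[[nd$param]]
        r <- cpp_bn_fwd(a, p$gamma, p$beta, p$rmean, p$rvar, 0.9, training,
                        1e-5)
        if (keep) caches[[id]] <- list(mean = r$mean, invstd = r$invstd)
        if (training) {
          bn_updates[[nd$param]] <- list(rmean = r$rmean, rvar = r$rvar)
        }
        r$y
      },
      relu = cpp_relu_fwd(a),
      maxpool = {
        r <- cpp_maxpool_fwd(a, nd$k, nd$stride, nd$pad)
        if (keep) caches[[id]] <- r$argmax
        r$y
      },
      concat = cpp_concat2(a, fetch(nd$inputs[2])),
      add = a + fetch(nd$inputs[2]),
      sigmoid = 1 / (1 + exp(-a)),
      stop("unknown op: ", nd$op)
    )
    acts[[id]] <- y
    if (!keep) {  # drop activations nothing later will read
      for (i in nd$inputs) if (i > 0L && last[i] <= id) acts[[i]] <- list(NULL)
    }
  }
  list(out = acts[[n]], acts = if (keep) acts, caches = caches,
       bn_updates = bn_updates)
}

# Backward pass. `seed_grads` is a list mapping node id (as character) to the
# gradient of the loss w.r.t. that node's output; gradients w.r.t. the network
# input are not computed. Returns per-parameter gradients.
nn_backward <- function(model, x, acts, caches, seed_grads) {
  nodes <- model$nodes
  n <- length(nodes)
  grads <- vector("list", n)
  for (nm in names(seed_grads)) grads[[as.integer(nm)]] <- seed_grads[[nm]]
  gparams <- list()
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    grads[[id]] <- NULL
    if (is.null(g)) {
      acts[[id]] <- list(NULL)
      next
    }
    nd <- nodes[[id]]
    in1 <- nd$inputs[1]
    ain <- if (in1 == 0L) x else acts[[in1]]
    push <- function(i, gi) {
      if (i == 0L) return(invisible(NULL))
      grads[[i]] <<- if (is.null(grads[[i]])) gi else grads[[i]] + gi
      invisible(NULL)
    }
    switch(nd$op,
      conv = {
        p <- model$params[[nd$param]]
        r <- cpp_conv2d_bwd(ain, p$W, g, nd$stride, nd$pad)
        gparams[[nd$param]] <- list(W = r$gw, b = r$gb)
        push(in1, r$gx)
      },
      convt = {
        p <- model$params[[nd$param]]
        r <- cpp_convt2_bwd(ain, p$W, g)
        gparams[[nd$param]] <- list(W = r$gw, b = r$gb)
        push(in1, r$gx)
      },
      bn = {
        p <- model$params[[nd$param]]
        cc <- caches[[id]]
        r <- cpp_bn_bwd(ain, p$gamma, cc$mean, cc$invstd, g)
        gparams[[nd$param]] <- list(gamma = r$ggamma, beta = r$gbeta)
        push(in1, r$gx)
      },
      relu = push(in1, cpp_relu_bwd(ain, g)),
      maxpool = push(in1, cpp_maxpool_bwd(caches[[id]], g, dim(ain))),
      concat = {
        c1 <- if (in1 == 0L) dim(x)[3] else dim(acts[[in1]])[3]
        push(in1, cpp_channel_slice(g, 1L, c1))
        push(nd$inputs[2], cpp_channel_slice(g, c1 + 1L, dim(g)[3]))
      },
      add = {
        push(in1, g)
        push(nd$inputs[2], g)
      },
      sigmoid = {
        y <- acts[[id]]
        push(in1, g * y * (1 - y))
      },
      stop("unknown op: ", nd$op)
    )
    acts[[id]] <- list(NULL)  # consumers are all behind us now
  }
  gparams
}

trainable_fields <- function(p) {
  if (p$type == "bn") c("gamma", "beta") else c("W", "b")
}

adam_state <- function(params) {
  lapply(params, function(p) {
    flds <- trainable_fields(p)
    stats::setNames(lapply(flds, function(f) {
      list(m = p[[f]] * 0, v = p[[f]] * 0)
    }), flds)
  })
}

adam_update <- function(params, gparams, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(gparams)) {
    gp <- gparams[[nm]]
    for (f in names(gp)) {
      g <- gp[[f]]
      st <- state[[nm]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[nm]][[f]] <- st
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m / (1 - beta1^t)) / (sqrt(st$v / (1 - beta2^t)) + eps)
    }
  }
  list(params = params, state = state)
}
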