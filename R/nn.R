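# Minimal purpose-built layer framework backing the 3D generators and
# discriminators. Layers are static descriptors; parameters live in a
# parallel tree so nets are pure values (update = replace the tree).
# Tensors are R arrays dim (d1, d2, d3, C); heavy ops call the compiled
# im2col/GEMM kernels, cheap elementwise ops stay in R.

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L) {
  list(kind = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

nn_convtr <- function(cin, cout, k = 3L, stride = 2L, pad = 1L, outpad = 1L) {
  list(kind = "convtr", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       outpad = as.integer(outpad))
}

# instance norm with an optionally fused activation (one kernel pass)
nn_inorm <- function(act = c("none", "relu", "lrelu"), eps = 1e-5,
                     alpha = 0.2) {
  act <- match.arg(act)
  list(kind = "inorm", eps = eps, alpha = alpha,
       act = match(act, c("none", "relu", "lrelu")) - 1L)
}
nn_relu <- function() list(kind = "relu")
nn_lrelu <- function(alpha = 0.2) list(kind = "lrelu", alpha = alpha)
nn_tanh <- function() list(kind = "tanh")
nn_sigmoid <- function() list(kind = "sigmoid")
nn_refpad <- function(p) list(kind = "refpad", p = as.integer(p))
nn_res <- function(layers) list(kind = "res", layers = layers)

# Weight init: N(0, 0.02) for conv kernels, zero bias (vanilla cycle-GAN
# convention). Uses the current R RNG stream.
nn_init <- function(layers, sd = 0.02) {
  lapply(layers, function(l) {
    switch(l$kind,
      conv = list(
        w = array(stats::rnorm(l$k^3 * l$cin * l$cout, sd = sd),
                  c(l$k, l$k, l$k, l$cin, l$cout)),
        b = numeric(l$cout)),
      convtr = list(
        w = array(stats::rnorm(l$k^3 * l$cout * l$cin, sd = sd),
                  c(l$k, l$k, l$k, l$cout, l$cin)),
        b = numeric(l$cout)),
      res = nn_init(l$layers, sd),
      NULL)
  })
}

nn_n_params <- function(params) {
  if (is.null(params)) return(0L)
  if (is.list(params)) return(sum(vapply(params, nn_n_params, 0)))
  length(params)
}

rep3 <- function(x) rep(as.integer(x), 3L)

layer_fwd <- function(l, p, x, float32 = TRUE) {
  switch(l$kind,
    conv = {
      y <- cn_conv3d_fwd(x, dim(x), p$w, dim(p$w), p$b,
                         rep3(l$stride), rep3(l$pad), float32)
      list(y = y, cache = x)
    },
    convtr = {
      y <- cn_convtr3d_fwd(x, dim(x), p$w, dim(p$w), p$b,
                           rep3(l$stride), rep3(l$pad), rep3(l$outpad),
                           float32)
      list(y = y, cache = x)
    },
    inorm = {
      r <- cn_inorm_act_fwd(x, dim(x), l$eps, l$act, l$alpha)
      list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd))
    },
    relu = { y <- cn_act_fwd(x, 0L, 0); list(y = y, cache = y) },
    lrelu = { y <- cn_act_fwd(x, 1L, l$alpha); list(y = y, cache = y) },
    tanh = { y <- cn_act_fwd(x, 2L, 0); list(y = y, cache = y) },
    sigmoid = { y <- cn_act_fwd(x, 3L, 0); list(y = y, cache = y) },
    refpad = list(y = cn_refpad_fwd(x, dim(x), l$p), cache = NULL),
    res = {
      r <- nn_forward(l$layers, p, x, float32)
      list(y = x + r$y, cache = r$caches)
    },
    stop("unknown layer kind: ", l$kind))
}

layer_bwd <- function(l, p, cache, gy, float32 = TRUE, need_gx = TRUE,
                      need_gw = TRUE) {
  switch(l$kind,
    conv = {
      r <- cn_conv3d_bwd(cache, dim(cache), p$w, dim(p$w), gy,
                         rep3(l$stride), rep3(l$pad), float32,
                         need_gx, need_gw)
      list(gx = if (need_gx) r$gx else NULL,
           grads = if (need_gw) list(w = r$gw, b = r$gb) else NULL)
    },
    convtr = {
      r <- cn_convtr3d_bwd(cache, dim(cache), p$w, dim(p$w), gy,
                           rep3(l$stride), rep3(l$pad), rep3(l$outpad),
                           float32, need_gx, need_gw)
      list(gx = if (need_gx) r$gx else NULL,
           grads = if (need_gw) list(w = r$gw, b = r$gb) else NULL)
    },
    inorm = list(gx = cn_inorm_act_bwd(cache$xhat, dim(cache$xhat),
                                       cache$istd, gy, l$act, l$alpha),
                 grads = NULL),
    relu = list(gx = cn_act_bwd(cache, gy, 0L, 0), grads = NULL),
    lrelu = list(gx = cn_act_bwd(cache, gy, 1L, l$alpha), grads = NULL),
    tanh = list(gx = cn_act_bwd(cache, gy, 2L, 0), grads = NULL),
    sigmoid = list(gx = cn_act_bwd(cache, gy, 3L, 0), grads = NULL),
    refpad = list(gx = cn_refpad_adj(gy, dim(gy), l$p), grads = NULL),
    res = {
      r <- nn_backward(l$layers, p, cache, gy, float32, need_gx = TRUE,
                       need_gw = need_gw)
      list(gx = gy + r$gx, grads = r$grads)
    },
    stop("unknown layer kind: ", l$kind))
}

nn_forward <- function(layers, params, x, float32 = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], params[[i]], x, float32)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

nn_backward <- function(layers, params, caches, gy, float32 = TRUE,
                        need_gx = TRUE, need_gw = TRUE) {
  grads <- vector("list", length(layers))
  # when the caller discards the input gradient, stop below the lowest
  # parameterized layer (nothing further needs an upstream gradient)
  lowest <- if (need_gx) 1L else {
    w <- which(!vapply(params, is.null, TRUE))
    if (length(w)) w[1] else length(layers) + 1L
  }
  for (i in rev(seq_along(layers))) {
    if (!need_gx && i < lowest) break
    r <- layer_bwd(layers[[i]], params[[i]], caches[[i]], gy, float32,
                   need_gx = need_gx || i > lowest, need_gw = need_gw)
    gy <- r$gx
    grads[i] <- list(r$grads)   # keep NULL slots (grads[[i]] <- NULL deletes)
  }
  list(gx = gy, grads = grads)
}

# ---- parameter-tree helpers ----

tree_map <- function(f, a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    return(out)
  }
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

tree_map3 <- function(f, a, b, c) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(f, a[[i]], b[[i]], c[[i]])
    return(out)
  }
  f(a, b, c)
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(`+`, a, b)
}

tree_max_abs <- function(a) {
  if (is.null(a)) return(0)
  if (is.list(a)) {
    vals <- vapply(a, tree_max_abs, 0)
    return(if (length(vals)) max(vals) else 0)
  }
  if (!length(a)) return(0)
  max(abs(a))
}

# ---- Adam ----

adam_new <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map3(
    function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(state = state, params = params)
}
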