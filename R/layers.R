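# Parameter initialisation and the shared forward-pass context.
#
# A model stores parameters in a flat named list (arrays) and batch-norm
# running statistics in a parallel list of environments. A forward pass
# wraps both in a context that caches one tape leaf per parameter so the
# backward pass can hand gradients back by name.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Kaiming-uniform fan-in initialisation for a (kh, kw, cin, cout) kernel.
init_conv_w <- function(kh, kw, cin, cout) {
  bound <- sqrt(6 / (kh * kw * cin))
  array(runif(kh * kw * cin * cout, -bound, bound), c(kh, kw, cin, cout))
}

init_dense_w <- function(cout, cin) {
  bound <- sqrt(6 / cin)
  matrix(runif(cout * cin, -bound, bound), cout, cin)
}

# builder: accumulates params/state while the architecture is declared
new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$params <- list()
  b$state <- list()
  b
}

add_conv <- function(b, name, kh, kw, cin, cout, bn = TRUE) {
  b$params[[paste0(name, ".w")]] <- init_conv_w(kh, kw, cin, cout)
  b$params[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    b$params[[paste0(name, ".gamma")]] <- rep(1, cout)
    b$params[[paste0(name, ".beta")]] <- numeric(cout)
    st <- new.env(parent = emptyenv())
    st$mean <- numeric(cout)
    st$var <- rep(1, cout)
    b$state[[name]] <- st
  }
  invisible(b)
}

add_dense <- function(b, name, cout, cin) {
  b$params[[paste0(name, ".w")]] <- init_dense_w(cout, cin)
  invisible(b)
}

# forward context ------------------------------------------------------------

new_ctx <- function(model, training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- ag_tape()
  ctx$model <- model
  ctx$training <- isTRUE(training)
  ctx$leaves <- new.env(parent = emptyenv())
  ctx
}

ctx_param <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    v <- ctx$model$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- ag_leaf(ctx$tape, v, pname = name)
    ctx$leaves[[name]] <- nd
  }
  nd
}

# conv -> [ReLU] -> [BN]; kernel geometry is read off the stored weight
fw_conv <- function(ctx, name, x, act = c("relu_bn", "plain", "relu")) {
  act <- match.arg(act)
  w <- ctx_param(ctx, paste0(name, ".w"))
  b <- ctx_param(ctx, paste0(name, ".b"))
  kd <- dim(w$value)
  y <- ag_conv2d(ctx$tape, x, w, b, ph = (kd[1] - 1L) %/% 2L,
                 pw = (kd[2] - 1L) %/% 2L)
  if (act != "plain") y <- ag_relu(ctx$tape, y)
  if (act == "relu_bn") {
    y <- ag_batchnorm(ctx$tape, y,
                      ctx_param(ctx, paste0(name, ".gamma")),
                      ctx_param(ctx, paste0(name, ".beta")),
                      ctx$model$state[[name]], ctx$training)
  }
  y
}

# collect gradients (by parameter name) after ag_backward
ctx_grads <- function(ctx) {
  out <- list()
  for (name in ls(ctx$leaves)) {
    g <- ctx$leaves[[name]]$grad
    if (!is.null(g)) out[[name]] <- g
  }
  out
}

# coerce a single (H, W, C) array or a list of them to a (H, W, C, N) batch
as_batch <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    out <- array(0, c(d, length(x)))
    for (i in seq_along(x)) out[, , , i] <- x[[i]]
    out
  } else if (length(dim(x)) == 3L) {
    array(x, c(dim(x), 1L))
  } else if (length(dim(x)) == 4L) {
    x
  } else if (is.matrix(x)) {
    array(x, c(dim(x), 1L, 1L))
  } else stop("expected an (H, W, C) array, (H, W, C, N) array, or list")
}
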