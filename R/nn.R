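# Two-layer perceptron blocks and the Adam optimizer used by the encoder and
# all task heads. Parameters live in plain named lists of numeric matrices;
# each training step registers them as tape leaves, runs forward/backward and
# applies Adam on the collected gradients.

#' Initialize a 2-layer perceptron block
#'
#' tanh hidden activation; optional output activation. Weights are drawn
#' from a scaled uniform (Glorot-style) distribution using the current RNG
#' state, biases start at zero.
#'
#' @param d_in,d_hidden,d_out integer widths.
#' @param out_act one of "linear", "tanh", "sigmoid".
#' @return named list of matrices `W1`, `b1`, `W2`, `b2` plus the activation.
#' @keywords internal
mlp_init <- function(d_in, d_hidden, d_out, out_act = "linear") {
  glorot <- function(a, b) {
    r <- sqrt(6 / (a + b))
    matrix(stats::runif(a * b, -r, r), a, b)
  }
  list(W1 = glorot(d_in, d_hidden), b1 = matrix(0, 1, d_hidden),
       W2 = glorot(d_hidden, d_out), b2 = matrix(0, 1, d_out),
       act = out_act)
}

# forward an MLP on the tape; `ids` holds tape leaf ids for this block's
# parameters (same names as the block), `x` a node id
mlp_forward <- function(tp, ids, block, x) {
  h <- tp_tanh(tp, tp_add_bias(tp, tp_matmul(tp, x, ids$W1), ids$b1))
  y <- tp_add_bias(tp, tp_matmul(tp, h, ids$W2), ids$b2)
  switch(block$act,
         linear = y,
         tanh = tp_tanh(tp, y),
         sigmoid = tp_sigmoid(tp, y),
         stop("unknown activation: ", block$act))
}

# ---- parameter trees --------------------------------------------------------

# flatten a nested list of matrices to a flat named list ("a.b.W1" keys)
params_flatten <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p)) {
      out <- c(out, params_flatten(p, key))
    } else if (is.matrix(p)) {
      out[[key]] <- p
    } # non-matrix entries (e.g. activation tags) are not trainable
  }
  out
}

assign_path <- function(l, path, value) {
  if (length(path) == 1L) {
    l[[path]] <- value
    return(l)
  }
  if (is.null(l[[path[1L]]])) l[[path[1L]]] <- list()
  l[[path[1L]]] <- assign_path(l[[path[1L]]], path[-1L], value)
  l
}

# register every matrix of a flat parameter list as a tape leaf
params_leaves <- function(tp, flat) {
  lapply(flat, function(m) tp_leaf(tp, m))
}

# rebuild the nested id structure so mlp_forward can address W1/b1/W2/b2
leaves_nest <- function(leaf_ids) {
  nested <- list()
  for (key in names(leaf_ids)) {
    nested <- assign_path(nested, strsplit(key, ".", fixed = TRUE)[[1]],
                          leaf_ids[[key]])
  }
  nested
}

# collect gradients for the leaves after tape_backward; zeros where unused
leaves_grads <- function(grads, leaf_ids, flat) {
  out <- flat
  for (key in names(leaf_ids)) {
    g <- grads[[leaf_ids[[key]]]]
    out[[key]] <- if (is.null(g)) 0 * flat[[key]] else g
  }
  out
}

# ---- Adam -------------------------------------------------------------------

#' Create Adam optimizer state for a flat parameter list
#' @keywords internal
adam_init <- function(flat, lr = 1e-2, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(flat, function(p) 0 * p),
       v = lapply(flat, function(p) 0 * p))
}

#' One Adam update; returns list(flat = updated params, opt = updated state)
#' @keywords internal
adam_step <- function(opt, flat, grads, trainable = names(flat)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (key in trainable) {
    g <- grads[[key]]
    opt$m[[key]] <- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
    opt$v[[key]] <- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g * g
    flat[[key]] <- flat[[key]] -
      opt$lr * (opt$m[[key]] / bc1) / (sqrt(opt$v[[key]] / bc2) + opt$eps)
  }
  list(flat = flat, opt = opt)
}
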