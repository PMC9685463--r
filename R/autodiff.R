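# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Nodes are
# referenced by integer id; each recorded op stores its parent ids and a
# backward closure mapping the incoming gradient to per-parent gradient
# contributions. A tape created with grad = FALSE records nothing and the
# same forward code doubles as plain inference.

#' Create a fresh autodiff tape
#'
#' @param grad logical; record backward closures (TRUE) or run forward-only.
#' @return an environment of class `egm_tape`.
#' @keywords internal
tape_new <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$backs <- vector("list", 256L)
  tp$n <- 0L
  tp$grad <- isTRUE(grad)
  class(tp) <- "egm_tape"
  tp
}

tp_push <- function(tp, value, parents = NULL, back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$backs) <- 2L * n
  }
  tp$vals[[n]] <- value
  if (tp$grad && !is.null(parents)) {
    tp$backs[[n]] <- list(parents = as.integer(parents), fn = back)
  }
  tp$n <- n
  n
}

tp_value <- function(tp, id) {
  force(id)  # id may be an op call that itself appends to the tape
  tp$vals[[id]]
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) == 1L) 1L else length(x))
}

#' Register a constant (no gradient) on the tape
#' @keywords internal
tp_const <- function(tp, x) tp_push(tp, as_mat(x))

#' Register a parameter leaf (gradient is collected for it)
#' @keywords internal
tp_leaf <- function(tp, x) tp_push(tp, as_mat(x), parents = integer(0), back = NULL)

# ---- elementwise / structural ops -------------------------------------------

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, va * vb, c(a, b),
          function(g) list(g * vb, g * va))
}

tp_div <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, va / vb, c(a, b),
          function(g) list(g / vb, -g * va / (vb * vb)))
}

# multiply matrix `a` (n x k) by column vector node `v` (n x 1), broadcast
# across columns
tp_mul_colvec <- function(tp, a, v) {
  force(a); force(v)
  va <- tp$vals[[a]]; vv <- tp$vals[[v]]
  tp_push(tp, va * as.vector(vv), c(a, v),
          function(g) list(g * as.vector(vv),
                           matrix(rowSums(g * va), ncol = 1L)))
}

# add a plain numeric (constant, recycled by R rules) to a node
tp_add_num <- function(tp, a, num) {
  force(a); force(num)
  tp_push(tp, tp$vals[[a]] + num, a, function(g) list(g))
}

tp_scale <- function(tp, a, s) {
  force(a); force(s)
  tp_push(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

# multiply by a constant column vector (recycled across columns)
tp_scale_rows <- function(tp, a, s) {
  force(a)
  s <- as.vector(s)
  tp_push(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

tp_matmul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), t(va) %*% g))
}

# add a 1 x k bias row to every row of an n x k matrix
tp_add_bias <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, sweep(va, 2L, as.vector(vb), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

tp_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp$vals[[a]])
  tp_push(tp, y, a, function(g) list(g * (1 - y * y)))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp$vals[[a]]))
  tp_push(tp, y, a, function(g) list(g * y * (1 - y)))
}

tp_exp <- function(tp, a) {
  force(a)
  y <- exp(tp$vals[[a]])
  tp_push(tp, y, a, function(g) list(g * y))
}

tp_log <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  tp_push(tp, log(va), a, function(g) list(g / va))
}

tp_sum <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  tp_push(tp, matrix(sum(va)), a,
          function(g) list(matrix(as.vector(g), nrow(va), ncol(va))))
}

tp_mean <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  n <- length(va)
  tp_push(tp, matrix(sum(va) / n), a,
          function(g) list(matrix(as.vector(g) / n, nrow(va), ncol(va))))
}

tp_rowsums <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  k <- ncol(va)
  tp_push(tp, matrix(rowSums(va), ncol = 1L), a,
          function(g) list(matrix(as.vector(g), nrow(va), k)))
}

# mean over rows -> 1 x k row vector
tp_colmeans <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  n <- nrow(va)
  tp_push(tp, matrix(colMeans(va), nrow = 1L), a,
          function(g) list(matrix(as.vector(g), n, ncol(va), byrow = TRUE) / n))
}

# gather rows by index
tp_rows <- function(tp, a, idx) {
  force(a); force(idx)
  va <- tp$vals[[a]]
  idx <- as.integer(idx)
  tp_push(tp, va[idx, , drop = FALSE], a,
          function(g) {
            out <- matrix(0, nrow(va), ncol(va))
            # accumulate duplicate indices
            for (col in seq_len(ncol(g))) {
              out[, col] <- out[, col] +
                as.vector(rowsum_into(g[, col], idx, nrow(va)))
            }
            list(out)
          })
}

# gather columns by index
tp_cols <- function(tp, a, idx) {
  force(a); force(idx)
  va <- tp$vals[[a]]
  idx <- as.integer(idx)
  tp_push(tp, va[, idx, drop = FALSE], a,
          function(g) {
            out <- matrix(0, nrow(va), ncol(va))
            for (k in seq_along(idx)) out[, idx[k]] <- out[, idx[k]] + g[, k]
            list(out)
          })
}

# sum rows of `a` into `nout` buckets given per-row bucket index
tp_scatter_rows <- function(tp, a, idx, nout) {
  force(a); force(idx)
  va <- tp$vals[[a]]
  idx <- as.integer(idx)
  val <- matrix(0, nout, ncol(va))
  for (col in seq_len(ncol(va))) {
    val[, col] <- rowsum_into(va[, col], idx, nout)
  }
  tp_push(tp, val, a, function(g) list(g[idx, , drop = FALSE]))
}

# dense helper: sum vector entries into n buckets (0 for empty buckets)
rowsum_into <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

tp_cbind <- function(tp, ...) {
  ids <- c(...)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, do.call(cbind, vals), ids,
          function(g) {
            lapply(seq_along(ids), function(k) {
              g[, starts[k]:ends[k], drop = FALSE]
            })
          })
}

tp_rbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tp_push(tp, do.call(rbind, vals), ids,
          function(g) {
            lapply(seq_along(ids), function(k) {
              g[starts[k]:ends[k], , drop = FALSE]
            })
          })
}

tp_sqrt <- function(tp, a) {
  force(a)
  y <- sqrt(tp$vals[[a]])
  tp_push(tp, y, a, function(g) list(g / (2 * pmax(y, 1e-12))))
}

# numerically stable log(1 + exp(x)); derivative is sigmoid(x)
tp_softplus <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  y <- pmax(va, 0) + log1p(exp(-abs(va)))
  sig <- 1 / (1 + exp(-va))
  tp_push(tp, y, a, function(g) list(g * sig))
}

# repeat a 1 x k row vector into n rows (broadcast); gradient sums over rows
tp_repeat_row <- function(tp, a, n) {
  force(a)
  va <- tp$vals[[a]]
  tp_push(tp, matrix(as.vector(va), n, ncol(va), byrow = TRUE), a,
          function(g) list(matrix(colSums(g), nrow = 1L)))
}

# numerically stable softmax of a column of logits grouped by `group`
# (values in 1..ngroup); returns a column of weights summing to 1 per group.
tp_group_softmax <- function(tp, z, group, ngroup) {
  force(z)
  group <- as.integer(group)
  zv <- as.vector(tp$vals[[z]])
  shift <- vapply(split(zv, group), max, numeric(1))[as.character(group)]
  e <- tp_exp(tp, tp_add_num(tp, z, -unname(shift)))
  s <- tp_scatter_rows(tp, e, group, ngroup)
  tp_div(tp, e, tp_rows(tp, s, group))
}

#' Run the backward pass from a scalar node
#'
#' @param tp tape; @param id node id of a 1x1 scalar.
#' @return list of gradients indexed by node id (NULL where unreached).
#' @keywords internal
tape_backward <- function(tp, id) {
  stopifnot(tp$grad, length(tp$vals[[id]]) == 1L)
  grads <- vector("list", tp$n)
  grads[[id]] <- matrix(1)
  for (i in seq.int(id, 1L)) {
    bk <- tp$backs[[i]]
    if (is.null(bk) || is.null(grads[[i]]) || length(bk$parents) == 0L) next
    contribs <- bk$fn(grads[[i]])
    for (k in seq_along(bk$parents)) {
      p <- bk$parents[k]
      ck <- contribs[[k]]
      if (is.null(ck)) next
      grads[[p]] <- if (is.null(grads[[p]])) ck else grads[[p]] + ck
    }
  }
  grads
}
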