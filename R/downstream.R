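# Downstream transfer: mean pooling over atoms, affinity regression (pK)
# and efficacy classification heads under linear-probing or fine-tuning,
# the per-complex motion statistic delta_x_LR, and the evaluation metrics.

#' Mean-pool encoded atom features into one complex representation
#'
#' @param features n x psi_h matrix of encoded features over all ligand and
#'   receptor atoms (or an `encoded_complex`).
#' @return numeric vector of width psi_h.
#' @export
pool_features <- function(features) {
  if (inherits(features, "encoded_complex")) features <- features$features
  if (is.null(nrow(features)) || nrow(features) == 0L) {
    stop("cannot pool an empty complex")
  }
  colMeans(features)
}

#' Convert a molar binding constant to pK
#'
#' pK = -log10(K), the PDBbind convention; K = 1e-6 M gives pK = 6.
#'
#' @param K inhibition/dissociation constant in molar units.
#' @return numeric pK.
#' @export
pK_from_constant <- function(K) -log10(K)

#' Per-complex motion statistic
#'
#' The mean squared per-atom displacement between encoder input and output
#' coordinates, Delta x_LR = ||x_out - x_in||_2^2 / (N + M). Smaller values
#' mean the model predicts a more static complex.
#'
#' @param x_in,x_out (N + M) x 3 coordinate matrices in the same atom order.
#' @return nonnegative scalar.
#' @export
delta_x_LR <- function(x_in, x_out) {
  if (!all(dim(x_in) == dim(x_out))) stop("coordinate shapes differ")
  sum((x_out - x_in)^2) / nrow(x_in)
}

#' Motion statistics for a set of complexes
#'
#' Encodes every snapshot with the model (no prompt) and reports the
#' motion statistic per complex.
#'
#' @param model an `egm_model` (or bare `egm_encoder`).
#' @param snapshots list of `complex_snapshot` objects.
#' @param ids optional identifiers.
#' @return data.frame with columns complex_id, delta_x_LR.
#' @export
egm_motion <- function(model, snapshots, ids = NULL) {
  encoder <- if (inherits(model, "egm_model")) model$encoder else model
  if (is.null(ids)) ids <- sprintf("cpx%03d", seq_along(snapshots))
  d <- vapply(snapshots, function(s) {
    delta_x_LR(snapshot_coords(s), egm_encode(encoder, s)$coords)
  }, numeric(1))
  data.frame(complex_id = ids, delta_x_LR = d)
}

#' Rank correlation between predicted motion and labels
#'
#' Spearman rank correlation between the motion statistic and the labels,
#' plus the least-squares line labels ~ delta_x_LR.
#'
#' @param delta numeric vector of motion statistics.
#' @param labels numeric labels (>= 10 required for a meaningful report).
#' @return list with `spearman`, `pearson`, `slope`, `intercept`, `n`.
#' @export
motion_label_correlation <- function(delta, labels) {
  if (length(delta) != length(labels)) stop("length mismatch")
  if (length(delta) < 10L) stop("need at least 10 labelled complexes")
  if (stats::sd(labels) == 0) stop("correlation undefined for constant labels")
  fit <- stats::lm(labels ~ delta)
  list(spearman = stats::cor(delta, labels, method = "spearman"),
       pearson = stats::cor(delta, labels),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(delta))
}

# ---- prediction heads -------------------------------------------------------

head_init <- function(psi_h, type = c("linear", "mlp"), hidden = 16L) {
  type <- match.arg(type)
  if (type == "linear") {
    list(type = "linear",
         params = list(W = matrix(0, psi_h, 1L), b = matrix(0, 1L, 1L)))
  } else {
    blk <- mlp_init(psi_h, hidden, 1L)
    list(type = "mlp", shapes = list(g = blk),
         params = params_flatten(list(g = blk)))
  }
}

head_forward <- function(tp, ids, head, H_id) {
  if (head$type == "linear") {
    tp_add_bias(tp, tp_matmul(tp, H_id, ids$W), ids$b)
  } else {
    mlp_forward(tp, ids$g, head$shapes$g, H_id)
  }
}

#' Fit a downstream prediction head on a pre-trained model
#'
#' Implements the two transfer protocols. Under `mode = "probe"` the
#' encoder is frozen: its parameters do not receive gradients and are
#' bit-identical after fitting; only the head (and, when
#' `train_prompt = TRUE`, the downstream prompt embedding) is trained.
#' Under `mode = "finetune"` all parameters are trainable. Affinity heads
#' minimize the batch RMSE of predicted pK; efficacy heads minimize binary
#' cross-entropy, with the efficacy region restriction applied by the
#' caller. Complexes are encoded with the downstream prompt when the model
#' was pre-trained with prompting.
#'
#' @param model a pre-trained `egm_model`.
#' @param snapshots list of `complex_snapshot` objects.
#' @param labels numeric vector: pK values (affinity) or 0/1 (efficacy).
#' @param task "affinity" or "efficacy".
#' @param mode "probe" or "finetune".
#' @param head_type "linear" (the probing default) or "mlp".
#' @param train_prompt also train the downstream prompt under probing.
#' @param steps,lr full-batch Adam steps and learning rate.
#' @return object of class `egm_head_fit`.
#' @export
egm_fit_head <- function(model, snapshots, labels,
                         task = c("affinity", "efficacy"),
                         mode = c("probe", "finetune"),
                         head_type = if (mode[1L] == "probe") "linear" else "mlp",
                         train_prompt = FALSE, steps = 200L, lr = 5e-2) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "egm_model"),
            length(snapshots) == length(labels), length(labels) >= 2L)
  psi_h <- model$encoder$config$psi_h
  head <- head_init(psi_h, head_type)
  y <- matrix(as.numeric(labels), ncol = 1L)

  use_prompt <- !is.null(model$prompts)
  prompt_vec <- if (use_prompt) {
    model$prompts$embeddings[downstream_prompt_row(model$prompts), ]
  } else NULL

  frozen_encoder <- (mode == "probe")
  static_features <- frozen_encoder && !train_prompt
  H_cache <- NULL
  if (static_features) {
    H_cache <- t(vapply(snapshots, function(s) {
      pool_features(egm_encode(model$encoder, s, prompt = prompt_vec))
    }, numeric(psi_h)))
  }

  flat <- c(lapply(stats::setNames(names(head$params),
                                   paste0("head.", names(head$params))),
                   function(k) head$params[[k]]))
  if (!static_features) flat <- c(flat, joint_params(model))
  trainable <- names(flat)[startsWith(names(flat), "head.")]
  if (mode == "finetune") trainable <- names(flat)
  if (frozen_encoder && train_prompt) {
    trainable <- c(trainable, "prompt.E")
  }

  opt <- adam_init(flat, lr = lr)
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    tp <- tape_new(grad = TRUE)
    leaf_ids <- params_leaves(tp, flat)
    nested <- leaves_nest(leaf_ids)
    H_id <- if (static_features) {
      tp_const(tp, H_cache)
    } else {
      pooled <- lapply(snapshots, function(snap) {
        H0 <- tp_const(tp, rbind(snap$ligand$features, snap$receptor$features))
        X0 <- tp_const(tp, snapshot_coords(snap))
        pr <- if (use_prompt) {
          tp_rows(tp, nested$prompt$E, downstream_prompt_row(model$prompts))
        } else NULL
        out <- encoder_forward(tp, nested$enc, model$encoder, H0, X0,
                               snapshot_edge_index(snap), pr)
        tp_colmeans(tp, out$H)
      })
      tp_rbind(tp, pooled)
    }
    z <- head_forward(tp, nested$head, head, H_id)
    loss <- if (task == "affinity") {
      r <- tp_sub(tp, z, tp_const(tp, y))
      tp_sqrt(tp, tp_mean(tp, tp_mul(tp, r, r)))
    } else {
      tp_mean(tp, tp_sub(tp, tp_softplus(tp, z),
                         tp_scale_rows(tp, z, as.vector(y))))
    }
    grads <- leaves_grads(tape_backward(tp, loss), leaf_ids, flat)
    upd <- adam_step(opt, flat, grads, trainable = trainable)
    flat <- upd$flat
    opt <- upd$opt
    hist[s] <- as.vector(tp_value(tp, loss))
  }

  for (k in names(flat)) {
    if (startsWith(k, "head.")) {
      head$params[[sub("^head\\.", "", k)]] <- flat[[k]]
    }
  }
  if (!static_features) {
    model <- set_joint_params(model, flat[!startsWith(names(flat), "head.")])
  }
  structure(list(model = model, head = head, task = task, mode = mode,
                 train_prompt = train_prompt, history = hist),
            class = "egm_head_fit")
}

#' @export
print.egm_head_fit <- function(x, ...) {
  cat(sprintf("<egm_head_fit> %s (%s head, %s): final loss %.4f after %d steps\n",
              x$task, x$head$type, x$mode, utils::tail(x$history, 1L),
              length(x$history)))
  invisible(x)
}

#' Predict with a fitted downstream head
#'
#' @param object an `egm_head_fit`.
#' @param snapshots list of `complex_snapshot` objects.
#' @param ... unused.
#' @return numeric vector: predicted pK (affinity) or probabilities in
#'   (0, 1), clamped to [1e-7, 1 - 1e-7] (efficacy).
#' @export
predict.egm_head_fit <- function(object, snapshots, ...) {
  model <- object$model
  prompt_vec <- if (!is.null(model$prompts)) {
    model$prompts$embeddings[downstream_prompt_row(model$prompts), ]
  } else NULL
  H <- t(vapply(snapshots, function(s) {
    pool_features(egm_encode(model$encoder, s, prompt = prompt_vec))
  }, numeric(model$encoder$config$psi_h)))
  tp <- tape_new(grad = FALSE)
  nested <- leaves_nest(params_leaves(
    tp, stats::setNames(object$head$params,
                        paste0("head.", names(object$head$params)))))
  z <- as.vector(tp_value(tp, head_forward(tp, nested$head, object$head,
                                           tp_const(tp, H))))
  if (object$task == "affinity") z
  else pmin(pmax(1 / (1 + exp(-z)), 1e-7), 1 - 1e-7)
}

# ---- metrics ----------------------------------------------------------------

#' Root-mean-squared error
#' @param pred,obs numeric vectors.
#' @export
rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

#' Area under the ROC curve by the rank statistic
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop("AUPRC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Standard downstream evaluation metrics
#'
#' @param pred predictions (pK or probabilities).
#' @param obs observed labels.
#' @param task "affinity" (RMSE, Pearson, Spearman) or "efficacy"
#'   (AUROC, AUPRC plus mean BCE).
#' @return named numeric vector.
#' @export
egm_metrics <- function(pred, obs, task = c("affinity", "efficacy")) {
  task <- match.arg(task)
  if (task == "affinity") {
    c(rmse = rmse(pred, obs),
      pearson = stats::cor(pred, obs),
      spearman = stats::cor(pred, obs, method = "spearman"))
  } else {
    c(auroc = auroc(pred, obs),
      auprc = auprc(pred, obs),
      bce = ordering_loss(pred, obs))
  }
}
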