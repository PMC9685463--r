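# Self-supervised pre-training: prompt-based denoising prediction of a
# future conformation (atom level) and snapshot ordering decoded by
# topological sort (conformation level). The two losses are mixed per batch
# with weight lambda and optimized jointly over the encoder, the prompt
# table and the ordering classifier with Adam.

#' Learnable prompt table over pre-defined time intervals
#'
#' One embedding row per time interval in `interval_set`, plus a distinct
#' downstream prompt row used when the pre-trained model is transferred to
#' a supervised task. Rows are initialized from N(0, 0.02^2).
#'
#' @param interval_set integer vector of time intervals (in frames).
#' @param psi_prompt embedding width.
#' @return object of class `prompt_table` with fields `interval_set` and
#'   `embeddings` ((length(interval_set) + 1) x psi_prompt; the final row is
#'   the downstream prompt).
#' @export
prompt_table <- function(interval_set = c(1L, 2L, 5L, 10L),
                         psi_prompt = 16L) {
  stopifnot(length(interval_set) >= 1L, all(interval_set >= 1L))
  k <- length(interval_set)
  structure(
    list(interval_set = as.integer(interval_set),
         embeddings = matrix(stats::rnorm((k + 1L) * psi_prompt, 0, 0.02),
                             k + 1L, psi_prompt)),
    class = "prompt_table")
}

prompt_row <- function(prompts, dt) {
  i <- match(dt, prompts$interval_set)
  if (is.na(i)) stop("no prompt embedding for interval ", dt)
  i
}

downstream_prompt_row <- function(prompts) nrow(prompts$embeddings)

#' Pre-training configuration
#'
#' @param sigma coordinate noise scale in Angstrom.
#' @param interval_set pre-defined prediction intervals (frames).
#' @param lambda mixing weight: loss = lambda * generation +
#'   (1 - lambda) * ordering.
#' @param n_order number of snapshots per ordering sample (n >= 2; n = 2
#'   degenerates to next-snapshot prediction).
#' @param steps optimization steps.
#' @param lr Adam learning rate.
#' @param batch_gen,batch_ord generation pairs / ordering samples per step.
#' @param use_generation,use_noise,use_prompt,use_ordering ablation
#'   toggles. With `use_noise = FALSE`, `use_prompt = FALSE` and
#'   `use_ordering = FALSE` the pipeline is the naive denoising-free
#'   next-frame generative task (intervals forced to {1}).
#' @param perturb_features also perturb invariant features.
#' @param psi_prompt prompt width (ignored when `use_prompt = FALSE`).
#' @param n_layers,hidden,max_step,clamp encoder hyper-parameters used when
#'   no encoder is supplied to [egm_pretrain()].
#' @return list of class `egm_pretrain_config`.
#' @export
egm_pretrain_config <- function(sigma = 0.1, interval_set = c(1L, 2L, 5L, 10L),
                                lambda = 0.5, n_order = 4L, steps = 200L,
                                lr = 1e-2, batch_gen = 2L, batch_ord = 1L,
                                use_generation = TRUE, use_noise = TRUE,
                                use_prompt = TRUE, use_ordering = TRUE,
                                perturb_features = FALSE, psi_prompt = 16L,
                                n_layers = 4L, hidden = 32L, max_step = 10,
                                clamp = TRUE) {
  if (!use_generation && !use_ordering) {
    stop("at least one pre-training task must be enabled")
  }
  stopifnot(lambda >= 0, lambda <= 1, n_order >= 2L, sigma >= 0)
  if (!use_prompt) interval_set <- 1L
  if (!use_noise) sigma <- 0
  structure(list(sigma = sigma, interval_set = as.integer(interval_set),
                 lambda = lambda, n_order = as.integer(n_order),
                 steps = as.integer(steps), lr = lr,
                 batch_gen = as.integer(batch_gen),
                 batch_ord = as.integer(batch_ord),
                 use_generation = use_generation, use_noise = use_noise,
                 use_prompt = use_prompt, use_ordering = use_ordering,
                 perturb_features = perturb_features,
                 psi_prompt = if (use_prompt) as.integer(psi_prompt) else 0L,
                 n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 max_step = max_step, clamp = clamp, k_context = 1L),
            class = "egm_pretrain_config")
}

#' Draw one generation training pair from a trajectory
#'
#' Samples a frame t and an interval dt from the configured interval set
#' (uniformly over the intervals feasible for the trajectory length, then
#' uniformly over feasible t with t + dt <= T), corrupts frame t with
#' N(0, sigma^2) coordinate noise, and returns the clean coordinates of
#' frame t + dt as the prediction target. The Markov context window is one
#' frame: only frame t enters the model input.
#'
#' @param traj a `trajectory`.
#' @param config an `egm_pretrain_config`.
#' @return list with `source` (corrupted `complex_snapshot`), `target`
#'   (clean n x 3 coordinate matrix), `t`, `dt`.
#' @export
sample_generation_pair <- function(traj, config) {
  T_len <- length(traj$snapshots)
  feasible <- config$interval_set[config$interval_set <= T_len - 1L]
  if (length(feasible) == 0L) {
    stop("trajectory too short for every interval in the interval set")
  }
  dt <- feasible[sample.int(length(feasible), 1L)]
  t <- sample.int(T_len - dt, 1L)
  src <- traj$snapshots[[t]]
  if (config$sigma > 0) {
    src <- perturb_snapshot(src, config$sigma, config$perturb_features)
  }
  list(source = src,
       target = snapshot_coords(traj$snapshots[[t + dt]]),
       t = t, dt = dt)
}

#' Denoising generation loss
#'
#' Mean squared per-atom coordinate displacement between prediction and
#' target: the Gaussian log-likelihood of the target under an isotropic
#' model, up to constants. An offset of (1,0,0) on every atom gives 1.
#'
#' @param predicted,target n x 3 coordinate matrices in the same atom order.
#' @return nonnegative scalar.
#' @export
generation_loss <- function(predicted, target) {
  if (!all(dim(predicted) == dim(target))) {
    stop("prediction and target shapes differ")
  }
  mean(rowSums((predicted - target)^2))
}

#' Initialize the pairwise ordering classifier
#'
#' A shared perceptron scorer g on concatenated pooled representations;
#' the pairwise logit is antisymmetrized as g(a, b) - g(b, a), so
#' P(a precedes b) + P(b precedes a) = 1 by construction.
#'
#' @param psi_h pooled representation width.
#' @param hidden hidden width.
#' @param seed optional seed for deterministic initialization.
#' @return object of class `order_classifier`.
#' @export
order_classifier <- function(psi_h = 9L, hidden = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- mlp_init(2L * psi_h, hidden, 1L)
  structure(list(psi_h = psi_h, shapes = list(g = g),
                 params = params_flatten(list(g = g))),
            class = "order_classifier")
}

#' Probability that snapshot a precedes snapshot b
#'
#' @param clf an `order_classifier`.
#' @param H_a,H_b pooled representation vectors.
#' @return probability in (0, 1).
#' @export
pairwise_order_prob <- function(clf, H_a, H_b) {
  tp <- tape_new(grad = FALSE)
  pids <- leaves_nest(params_leaves(tp, clf$params))
  ab <- tp_const(tp, matrix(c(H_a, H_b), nrow = 1L))
  ba <- tp_const(tp, matrix(c(H_b, H_a), nrow = 1L))
  z <- tp_value(tp, mlp_forward(tp, pids$g, clf$shapes$g, ab)) -
       tp_value(tp, mlp_forward(tp, pids$g, clf$shapes$g, ba))
  1 / (1 + exp(-as.vector(z)))
}

#' Ordering loss over a set of pairwise constraints
#'
#' Mean binary cross-entropy of the predicted precedence probabilities
#' against the true before/after labels; probabilities are clamped to
#' [1e-7, 1 - 1e-7] for stability.
#'
#' @param probs vector of predicted P(a precedes b), one per constraint.
#' @param labels 0/1 vector of the true precedence relations.
#' @return nonnegative scalar.
#' @export
ordering_loss <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop("one probability is required per constraint")
  }
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# Kahn's topological sort with smallest-index tie-break; NULL if cyclic
topo_sort <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  used <- rep(FALSE, n)
  ord <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(!used & indeg == 0)
    if (length(cand) == 0L) return(NULL)
    v <- cand[1L]
    used[v] <- TRUE
    ord <- c(ord, v)
    indeg[adj[v, ]] <- indeg[adj[v, ]] - 1L
  }
  ord
}

# exact maximization of the coherence objective sum log P over implied
# pairs, by dynamic programming over subsets of still-unplaced items;
# ties resolved toward the smallest item index placed first
order_exact <- function(P) {
  n <- nrow(P)
  if (n > 12L) stop("exact coherence decoding is limited to n <= 12")
  logP <- log(pmax(P, 1e-12))
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  nset <- bitwShiftL(1L, n)
  # g[S + 1] = best score for ordering the item set with bitmask S; placing
  # v first contributes sum(logP[v, rest of S])
  g <- numeric(nset)
  members <- lapply(0:(nset - 1L), function(S) which(bitwAnd(S, bit) != 0L))
  ord_sets <- order(vapply(members, length, integer(1)))  # by subset size
  for (S in (ord_sets - 1L)) {
    rem <- members[[S + 1L]]
    if (length(rem) < 2L) next
    g[S + 1L] <- max(vapply(rem, function(v) {
      others <- rem[rem != v]
      sum(logP[v, others]) + g[S - bit[v] + 1L]
    }, numeric(1)))
  }
  ord <- integer(n)
  S <- nset - 1L
  for (k in seq_len(n)) {
    rem <- members[[S + 1L]]
    scores <- vapply(rem, function(v) {
      others <- rem[rem != v]
      (if (length(others)) sum(logP[v, others]) else 0) + g[S - bit[v] + 1L]
    }, numeric(1))
    v <- rem[scores >= max(scores) - 1e-12][1L]
    ord[k] <- v
    S <- S - bit[v]
  }
  ord
}

#' Decode a snapshot order from pairwise precedence probabilities
#'
#' Builds a directed graph with an edge a -> b wherever
#' P(a precedes b) > 0.5 and, when that graph is acyclic, returns its
#' topological order (Kahn's algorithm, smallest item index first among
#' ties) -- which provably maximizes the coherence objective
#' sum of log P over the implied pairs. When the graph contains cycles no
#' topological order exists; the default `method = "coherence"` then
#' maximizes the coherence objective exactly by dynamic programming over
#' item subsets (equivalent to removing a minimum-weight feedback arc
#' set), while `method = "greedy"` instead repeatedly removes the
#' lowest-confidence edge (minimal |P - 0.5|, ties by smallest item
#' indices) until a topological order exists. With n = 2 the task reduces
#' to next-snapshot prediction.
#'
#' @param P n x n matrix with P[a, b] = predicted probability that a
#'   precedes b (only the relative values of symmetric entries matter).
#' @param method cycle resolution strategy, see above.
#' @return integer permutation of 1..n.
#' @export
decode_order <- function(P, method = c("coherence", "greedy")) {
  method <- match.arg(method)
  n <- nrow(P)
  if (is.null(n) || n < 2L) stop("ordering needs at least two items")
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (P[a, b] > 0.5) adj[a, b] <- TRUE
      else if (P[b, a] > 0.5) adj[b, a] <- TRUE
    }
  }
  ord <- topo_sort(adj)
  if (!is.null(ord)) return(ord)
  if (method == "coherence") return(order_exact(P))
  repeat {
    e <- which(adj, arr.ind = TRUE)
    conf <- abs(P[e] - 0.5)
    pick <- order(conf, e[, 1L], e[, 2L])[1L]
    adj[e[pick, 1L], e[pick, 2L]] <- FALSE
    ord <- topo_sort(adj)
    if (!is.null(ord)) return(ord)
  }
}

#' Build an ordering sample from a trajectory
#'
#' Draws `n` distinct frames, presents them in shuffled order, and lists
#' all n(n-1)/2 pairwise precedence constraints with their true labels.
#'
#' @param traj a `trajectory`.
#' @param n number of snapshots.
#' @return list with `snapshots` (shuffled), `true_order` (permutation
#'   recovering temporal order), and `constraints` (data.frame a, b,
#'   label = 1 if shuffled item a temporally precedes item b).
#' @export
sample_ordering <- function(traj, n = 4L) {
  T_len <- length(traj$snapshots)
  if (n < 2L || n > T_len) stop("need 2 <= n <= number of frames")
  frames <- sort(sample.int(T_len, n))
  shuffle <- sample.int(n)
  snaps <- traj$snapshots[frames][shuffle]
  times <- frames[shuffle]
  pairs <- utils::combn(n, 2L)
  constraints <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                            label = as.integer(times[pairs[1L, ]] <
                                               times[pairs[2L, ]]))
  list(snapshots = snaps, true_order = order(times),
       constraints = constraints)
}

# ---- joint training step ----------------------------------------------------

# Build the combined loss on a tape for one batch. `flat` is the joint flat
# parameter list with prefixes enc. / prompt. / ord.; returns loss node ids
# and the bookkeeping needed for backward.
pretrain_batch_tape <- function(tp, flat, model, gen_pairs, ord_samples) {
  cfg <- model$config
  encoder <- model$encoder
  leaf_ids <- params_leaves(tp, flat)
  nested <- leaves_nest(leaf_ids)
  gen_ids <- list()
  if (length(gen_pairs)) {
    for (gp in gen_pairs) {
      snap <- gp$source
      H0 <- tp_const(tp, rbind(snap$ligand$features, snap$receptor$features))
      X0 <- tp_const(tp, snapshot_coords(snap))
      pr <- if (cfg$use_prompt) {
        tp_rows(tp, nested$prompt$E, prompt_row(model$prompts, gp$dt))
      } else NULL
      out <- encoder_forward(tp, nested$enc, encoder, H0, X0,
                             snapshot_edge_index(snap), pr)
      diff <- tp_sub(tp, out$X, tp_const(tp, gp$target))
      gen_ids[[length(gen_ids) + 1L]] <-
        tp_scale(tp, tp_sum(tp, tp_mul(tp, diff, diff)), 1 / nrow(gp$target))
    }
  }
  ord_ids <- list()
  if (length(ord_samples)) {
    for (os in ord_samples) {
      pooled <- lapply(os$snapshots, function(snap) {
        H0 <- tp_const(tp, rbind(snap$ligand$features, snap$receptor$features))
        X0 <- tp_const(tp, snapshot_coords(snap))
        out <- encoder_forward(tp, nested$enc, encoder, H0, X0,
                               snapshot_edge_index(snap), NULL)
        tp_colmeans(tp, out$H)
      })
      Hmat <- tp_rbind(tp, pooled)
      a <- os$constraints$a; b <- os$constraints$b
      AB <- tp_cbind(tp, tp_rows(tp, Hmat, a), tp_rows(tp, Hmat, b))
      BA <- tp_cbind(tp, tp_rows(tp, Hmat, b), tp_rows(tp, Hmat, a))
      z <- tp_sub(tp, mlp_forward(tp, nested$ord$g, model$order_clf$shapes$g, AB),
                      mlp_forward(tp, nested$ord$g, model$order_clf$shapes$g, BA))
      # BCE from logits: mean(softplus(z) - y * z)
      y <- os$constraints$label
      ord_ids[[length(ord_ids) + 1L]] <-
        tp_mean(tp, tp_sub(tp, tp_softplus(tp, z), tp_scale_rows(tp, z, y)))
    }
  }
  mean_nodes <- function(ids) {
    if (length(ids) == 0L) return(NULL)
    acc <- ids[[1L]]
    for (i in ids[-1L]) acc <- tp_add(tp, acc, i)
    tp_scale(tp, acc, 1 / length(ids))
  }
  gen_loss <- mean_nodes(gen_ids)
  ord_loss <- mean_nodes(ord_ids)
  loss <- if (!is.null(gen_loss) && !is.null(ord_loss)) {
    tp_add(tp, tp_scale(tp, gen_loss, cfg$lambda),
               tp_scale(tp, ord_loss, 1 - cfg$lambda))
  } else if (!is.null(gen_loss)) gen_loss else ord_loss
  list(loss = loss, gen = gen_loss, ord = ord_loss, leaf_ids = leaf_ids)
}

# one optimization step; returns updated model/optimizer plus loss values
pretrain_step <- function(model, opt, trajectories) {
  cfg <- model$config
  gen_pairs <- list()
  if (cfg$use_generation) {
    for (i in seq_len(cfg$batch_gen)) {
      traj <- trajectories[[sample.int(length(trajectories), 1L)]]
      gen_pairs[[i]] <- sample_generation_pair(traj, cfg)
    }
  }
  ord_samples <- list()
  if (cfg$use_ordering) {
    for (i in seq_len(cfg$batch_ord)) {
      traj <- trajectories[[sample.int(length(trajectories), 1L)]]
      ord_samples[[i]] <- sample_ordering(traj, cfg$n_order)
    }
  }
  flat <- joint_params(model)
  tp <- tape_new(grad = TRUE)
  built <- pretrain_batch_tape(tp, flat, model, gen_pairs, ord_samples)
  grads_all <- tape_backward(tp, built$loss)
  grads <- leaves_grads(grads_all, built$leaf_ids, flat)
  upd <- adam_step(opt, flat, grads)
  model <- set_joint_params(model, upd$flat)
  list(model = model, opt = upd$opt,
       loss = as.vector(tp_value(tp, built$loss)),
       gen = if (is.null(built$gen)) NA_real_ else as.vector(tp_value(tp, built$gen)),
       ord = if (is.null(built$ord)) NA_real_ else as.vector(tp_value(tp, built$ord)))
}

joint_params <- function(model) {
  flat <- list()
  for (k in names(model$encoder$params)) {
    flat[[paste0("enc.", k)]] <- model$encoder$params[[k]]
  }
  if (!is.null(model$prompts)) flat[["prompt.E"]] <- model$prompts$embeddings
  if (!is.null(model$order_clf)) {
    for (k in names(model$order_clf$params)) {
      flat[[paste0("ord.", k)]] <- model$order_clf$params[[k]]
    }
  }
  flat
}

set_joint_params <- function(model, flat) {
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    rest <- paste(parts[-1L], collapse = ".")
    if (parts[1L] == "enc") model$encoder$params[[rest]] <- flat[[k]]
    else if (parts[1L] == "prompt") model$prompts$embeddings <- flat[[k]]
    else if (parts[1L] == "ord") model$order_clf$params[[rest]] <- flat[[k]]
  }
  model
}

#' Pre-train an equivariant graph matching model on MD-like trajectories
#'
#' The main fitting function. Jointly optimizes the encoder, the prompt
#' table and the ordering classifier with Adam on the mixed objective
#' lambda * generation + (1 - lambda) * ordering, sampling generation pairs
#' and ordering samples uniformly across the supplied trajectories.
#'
#' @param trajectories list of `trajectory` objects (or a single one).
#' @param config an [egm_pretrain_config()].
#' @param encoder optional pre-built [egm_encoder()]; default constructs one
#'   matching the trajectories' feature width.
#' @param seed optional integer seed governing initialization and sampling.
#' @return object of class `egm_model` with components `encoder`, `prompts`,
#'   `order_clf`, `config` and `history` (per-step loss data.frame).
#' @seealso [predict.egm_model()], [egm_fit_head()], [delta_x_LR()]
#' @export
egm_pretrain <- function(trajectories, config = egm_pretrain_config(),
                         encoder = NULL, seed = NULL) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, logical(1), "trajectory")))
  if (!is.null(seed)) set.seed(seed)
  psi_h <- ncol(trajectories[[1L]]$snapshots[[1L]]$ligand$features)
  if (is.null(encoder)) {
    encoder <- egm_encoder(psi_h = psi_h, n_layers = config$n_layers,
                           hidden = config$hidden,
                           psi_prompt = config$psi_prompt,
                           max_step = config$max_step, clamp = config$clamp)
  }
  model <- structure(
    list(encoder = encoder,
         prompts = if (config$use_prompt) {
           prompt_table(config$interval_set, config$psi_prompt)
         } else NULL,
         order_clf = if (config$use_ordering) {
           order_classifier(psi_h = encoder$config$psi_h,
                            hidden = encoder$config$hidden)
         } else NULL,
         config = config, history = NULL),
    class = "egm_model")
  opt <- adam_init(joint_params(model), lr = config$lr)
  hist <- data.frame(step = seq_len(config$steps), loss = NA_real_,
                     generation = NA_real_, ordering = NA_real_)
  for (s in seq_len(config$steps)) {
    st <- pretrain_step(model, opt, trajectories)
    model <- st$model
    opt <- st$opt
    hist$loss[s] <- st$loss
    hist$generation[s] <- st$gen
    hist$ordering[s] <- st$ord
  }
  model$history <- hist
  model
}

#' @export
print.egm_model <- function(x, ...) {
  cfg <- x$config
  cat("<egm_model> pre-trained equivariant graph matching model\n")
  print(x$encoder)
  cat(sprintf("  tasks: generation=%s (sigma=%.3g, prompt=%s), ordering=%s (n=%d), lambda=%.2f\n",
              cfg$use_generation, cfg$sigma, cfg$use_prompt,
              cfg$use_ordering, cfg$n_order, cfg$lambda))
  if (!is.null(x$history)) {
    cat(sprintf("  %d steps; final loss %.4f\n", nrow(x$history),
                utils::tail(x$history$loss, 1L)))
  }
  invisible(x)
}

#' @export
summary.egm_model <- function(object, ...) {
  h <- object$history
  cat("Pre-training loss summary\n")
  print(summary(h[, c("loss", "generation", "ordering")]))
  invisible(object)
}

#' @export
coef.egm_model <- function(object, ...) joint_params(object)

#' Plot the pre-training loss history
#' @param x an `egm_model`; @param ... passed to `matplot`.
#' @export
plot.egm_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$step, h[, c("loss", "generation", "ordering")],
                    type = "l", lty = 1, xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", c("combined", "generation", "ordering"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Encode snapshots with a pre-trained model
#'
#' @param object an `egm_model`.
#' @param snapshot a `complex_snapshot`.
#' @param type "encoding" returns the full `encoded_complex`; "pooled" the
#'   mean-pooled representation vector; "coords" the predicted coordinates.
#' @param prompt "none", "downstream" (the transfer prompt h*), or an
#'   integer interval from the prompt table.
#' @param ... unused.
#' @export
predict.egm_model <- function(object, snapshot,
                              type = c("encoding", "pooled", "coords"),
                              prompt = "none", ...) {
  type <- match.arg(type)
  pr <- NULL
  if (!is.null(object$prompts) && !identical(prompt, "none")) {
    row <- if (identical(prompt, "downstream")) {
      downstream_prompt_row(object$prompts)
    } else prompt_row(object$prompts, prompt)
    pr <- object$prompts$embeddings[row, ]
  }
  enc <- egm_encode(object$encoder, snapshot, prompt = pr)
  switch(type,
         encoding = enc,
         pooled = colMeans(enc$features),
         coords = enc$coords)
}
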