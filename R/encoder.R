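# The E(3)-equivariant graph matching encoder. Each of the L layers passes
# invariant messages along intra-graph edges, attention-weighted messages
# along cross-graph (ligand-receptor) edges, moves coordinates along
# relative-position vectors scaled by learned invariant weights, and updates
# invariant features from the aggregated messages. All learned sub-networks
# consume only E(3)-invariant quantities (features and squared distances),
# so feature outputs are rigid-motion invariant and coordinate outputs are
# rigid-motion equivariant by construction.

#' Initialize an equivariant graph matching encoder
#'
#' Creates the layered encoder state: per layer, 2-layer perceptron blocks
#' for the edge operation (phi_e), node operation (phi_h), intra and cross
#' coordinate-weight operations (phi_m, phi_mu), the distance operation
#' (phi_d) and the attention query/key maps (phi_q, phi_k). When a prompt
#' of width `psi_prompt` is in use, it is appended to every atom's feature
#' vector before layer 1, so the layer-1 blocks consume width
#' `psi_h + psi_prompt`.
#'
#' @param psi_h invariant feature width (must match the atom feature width
#'   of the graphs to be encoded; 9 for the default element vocabulary).
#' @param n_layers number of message-passing layers L (default 4).
#' @param hidden hidden width of every sub-network perceptron.
#' @param psi_prompt width of prompt embeddings (0 disables prompting).
#' @param max_step clamp on the per-atom coordinate step length per layer,
#'   in Angstrom; guards against early-training divergence.
#' @param clamp logical; disable for the strict unclamped update form.
#' @param seed optional integer; parameter initialization is drawn after
#'   `set.seed(seed)` for deterministic construction.
#' @return object of class `egm_encoder`.
#' @export
egm_encoder <- function(psi_h = 9L, n_layers = 4L, hidden = 32L,
                        psi_prompt = 16L, max_step = 10, clamp = TRUE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w1 <- psi_h + psi_prompt   # layer-1 input width (prompt slots appended)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    w_in <- if (l == 1L) w1 else psi_h
    # cross messages are elementwise products with h_j, so their width (and
    # phi_d's output) follows the layer input width w_in, which carries the
    # prompt slots at layer 1
    layers[[l]] <- list(
      phi_e  = mlp_init(2L * w_in + 1L, hidden, psi_h),
      phi_h  = mlp_init(2L * w_in + psi_h, hidden, psi_h),
      phi_m  = mlp_init(psi_h, hidden, 1L, out_act = "tanh"),
      phi_mu = mlp_init(w_in, hidden, 1L, out_act = "tanh"),
      phi_d  = mlp_init(1L, hidden, w_in),
      phi_q  = mlp_init(w_in, hidden, psi_h),
      phi_k  = mlp_init(w_in, hidden, psi_h)
    )
  }
  if (n_layers > 0L) names(layers) <- paste0("L", seq_len(n_layers))
  structure(
    list(config = list(psi_h = psi_h, n_layers = n_layers, hidden = hidden,
                       psi_prompt = psi_prompt, max_step = max_step,
                       clamp = clamp),
         params = params_flatten(list(layers = layers)),
         shapes = list(layers = layers)),
    class = "egm_encoder")
}

#' @export
print.egm_encoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<egm_encoder> %d layers, psi_h=%d, psi_prompt=%d, hidden=%d (%d parameters)\n",
    cfg$n_layers, cfg$psi_h, cfg$psi_prompt, cfg$hidden,
    sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

# global edge index sets of a snapshot: ligand atoms 1..N, receptor N+1..N+M
snapshot_edge_index <- function(snapshot) {
  n_l <- length(snapshot$ligand$elements)
  n <- n_atoms(snapshot)
  intra <- rbind(snapshot$ligand$intra_edges,
                 snapshot$receptor$intra_edges + n_l)
  ce <- snapshot$cross_edges
  cross <- rbind(cbind(ce[, 1L], ce[, 2L] + n_l),
                 cbind(ce[, 2L] + n_l, ce[, 1L]))
  deg <- tabulate(c(intra[, 1L], cross[, 1L]), nbins = n)
  list(intra = intra, cross = cross, deg = deg, n = n)
}

# forward pass on an autodiff tape; `pids` is the nested leaf-id structure
# mirroring encoder$shapes, H_id / X_id node ids for the stacked features
# (n x psi_h) and coordinates (n x 3), `prompt_id` an optional 1 x
# psi_prompt node id.
encoder_forward <- function(tp, pids, encoder, H_id, X_id, edges,
                            prompt_id = NULL) {
  cfg <- encoder$config
  shapes <- encoder$shapes$layers
  n <- edges$n
  psi <- cfg$psi_h
  H <- H_id
  if (cfg$psi_prompt > 0L) {
    pr <- if (is.null(prompt_id)) {
      tp_const(tp, matrix(0, 1L, cfg$psi_prompt))
    } else prompt_id
    H <- tp_cbind(tp, H, tp_repeat_row(tp, pr, n))
  }
  X <- X_id
  inv_deg <- 1 / pmax(edges$deg, 1L)
  zero_msg <- function(w) tp_const(tp, matrix(0, n, w))

  for (l in seq_len(cfg$n_layers)) {
    p <- pids$layers[[l]]
    s <- shapes[[l]]
    has_intra <- nrow(edges$intra) > 0L
    has_cross <- nrow(edges$cross) > 0L

    if (has_intra) {
      di <- edges$intra[, 1L]; si <- edges$intra[, 2L]
      Hi <- tp_rows(tp, H, di); Hj <- tp_rows(tp, H, si)
      Di <- tp_sub(tp, tp_rows(tp, X, di), tp_rows(tp, X, si))
      d2i <- tp_rowsums(tp, tp_mul(tp, Di, Di))
      M <- mlp_forward(tp, p$phi_e, s$phi_e, tp_cbind(tp, Hi, Hj, d2i))
      w_m <- mlp_forward(tp, p$phi_m, s$phi_m, M)
      Msum <- tp_scatter_rows(tp, M, di, n)
      rel_intra <- tp_scatter_rows(tp, tp_mul_colvec(tp, Di, w_m), di, n)
    } else {
      Msum <- zero_msg(psi)
      rel_intra <- NULL
    }

    if (has_cross) {
      dc <- edges$cross[, 1L]; sc <- edges$cross[, 2L]
      Hic <- tp_rows(tp, H, dc); Hjc <- tp_rows(tp, H, sc)
      Dc <- tp_sub(tp, tp_rows(tp, X, dc), tp_rows(tp, X, sc))
      d2c <- tp_rowsums(tp, tp_mul(tp, Dc, Dc))
      q <- mlp_forward(tp, p$phi_q, s$phi_q, Hic)
      k <- mlp_forward(tp, p$phi_k, s$phi_k, Hjc)
      a <- tp_group_softmax(tp, tp_rowsums(tp, tp_mul(tp, q, k)), dc, n)
      phd <- mlp_forward(tp, p$phi_d, s$phi_d, d2c)
      MU <- tp_mul_colvec(tp, tp_mul(tp, Hjc, phd), a)
      w_mu <- mlp_forward(tp, p$phi_mu, s$phi_mu, MU)
      MUsum <- tp_scatter_rows(tp, MU, dc, n)
      rel_cross <- tp_scatter_rows(tp, tp_mul_colvec(tp, Dc, w_mu), dc, n)
    } else {
      MUsum <- zero_msg(ncol(tp_value(tp, H)))
      rel_cross <- NULL
    }

    # coordinate update: degree-normalized sum of weighted relative
    # positions over all incident edges (intra and cross pooled)
    S <- if (!is.null(rel_intra) && !is.null(rel_cross)) {
      tp_add(tp, rel_intra, rel_cross)
    } else if (!is.null(rel_intra)) rel_intra
    else if (!is.null(rel_cross)) rel_cross
    else NULL
    if (!is.null(S)) {
      fac <- inv_deg
      if (isTRUE(cfg$clamp)) {
        step_len <- sqrt(rowSums(tp_value(tp, S)^2)) * inv_deg
        fac <- fac * pmin(1, cfg$max_step / pmax(step_len, 1e-12))
      }
      X <- tp_add(tp, X, tp_scale_rows(tp, S, fac))
    }

    # feature update with residual connection; layer 1 drops prompt slots
    # from the residual path so widths stay psi_h
    Hres <- if (ncol(tp_value(tp, H)) != psi) tp_cols(tp, H, seq_len(psi)) else H
    H <- tp_add(tp, Hres,
                mlp_forward(tp, p$phi_h, s$phi_h, tp_cbind(tp, H, Msum, MUsum)))
  }
  list(H = H, X = X)
}

#' Encode a complex snapshot
#'
#' Runs the full L-layer forward pass and returns the transformed invariant
#' features and coordinates. During pre-training the output coordinates are
#' interpreted as the predicted future conformation.
#'
#' @param encoder an `egm_encoder`.
#' @param snapshot a `complex_snapshot`.
#' @param prompt optional numeric prompt vector of width `psi_prompt`,
#'   appended to every atom's features before layer 1.
#' @return list of class `encoded_complex` with `features` (n x psi_h),
#'   `coords` (n x 3, Angstrom), and the ligand atom count `n_ligand`.
#' @export
egm_encode <- function(encoder, snapshot, prompt = NULL) {
  stopifnot(inherits(encoder, "egm_encoder"),
            inherits(snapshot, "complex_snapshot"))
  feats <- rbind(snapshot$ligand$features, snapshot$receptor$features)
  if (ncol(feats) != encoder$config$psi_h) {
    stop("feature width ", ncol(feats), " does not match encoder psi_h ",
         encoder$config$psi_h)
  }
  if (!is.null(prompt) && length(prompt) != encoder$config$psi_prompt) {
    stop("prompt width must equal psi_prompt")
  }
  tp <- tape_new(grad = FALSE)
  pids <- leaves_nest(params_leaves(tp, encoder$params))
  H0 <- tp_const(tp, feats)
  X0 <- tp_const(tp, snapshot_coords(snapshot))
  pr <- if (is.null(prompt)) NULL else tp_const(tp, matrix(prompt, nrow = 1L))
  out <- encoder_forward(tp, pids, encoder, H0, X0,
                         snapshot_edge_index(snapshot), pr)
  structure(list(features = tp_value(tp, out$H),
                 coords = tp_value(tp, out$X),
                 n_ligand = length(snapshot$ligand$elements)),
            class = "encoded_complex")
}

#' @export
print.encoded_complex <- function(x, ...) {
  cat(sprintf("<encoded_complex> %d atoms, feature width %d\n",
              nrow(x$coords), ncol(x$features)))
  invisible(x)
}
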