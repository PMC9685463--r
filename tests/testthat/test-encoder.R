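# equivariant graph matching encoder: symmetry properties and message
# mechanics

test_that("encoding is E(3) equivariant and feature-invariant", {
  set.seed(201)
  enc <- egm_encoder(psi_h = 9, n_layers = 3, hidden = 8, psi_prompt = 4,
                     seed = 7)
  for (rep in 1:5) {
    snap <- random_complex()
    R <- random_rotation(); tau <- rnorm(3)
    e1 <- egm_encode(enc, snap)
    e2 <- egm_encode(enc, transform_snapshot(snap, R, tau))
    expect_lt(max(abs(e2$features - e1$features)), 1e-5)
    expect_lt(max(abs(e2$coords - sweep(e1$coords %*% t(R), 2, tau, "+"))),
              1e-5)
  }
})

test_that("encoding is equivariant to atom permutations within each graph", {
  set.seed(202)
  enc <- egm_encoder(psi_h = 9, n_layers = 2, hidden = 8, psi_prompt = 0,
                     seed = 3)
  lig <- random_graph(5, spread = 1.5)
  rec <- random_graph(10, spread = 3)
  snap <- complex_snapshot(lig, rec)
  e1 <- egm_encode(enc, snap)
  perm <- sample(5)
  ligp <- molecular_graph(lig$elements[perm], lig$coords[perm, , drop = FALSE])
  e2 <- egm_encode(enc, complex_snapshot(ligp, rec))
  expect_lt(max(abs(e2$features[seq_len(5), ] - e1$features[perm, ])), 1e-6)
  expect_lt(max(abs(e2$coords[seq_len(5), ] - e1$coords[perm, ])), 1e-6)
  expect_lt(max(abs(e2$features[-seq_len(5), ] - e1$features[-seq_len(5), ])),
            1e-6)
})

test_that("zero layers give the identity and zeroed coordinate nets decouple", {
  set.seed(203)
  snap <- random_complex()
  id_enc <- egm_encoder(psi_h = 9, n_layers = 0, hidden = 8, psi_prompt = 0)
  e0 <- egm_encode(id_enc, snap)
  expect_identical(e0$coords, egmatch:::snapshot_coords(snap))
  expect_identical(e0$features,
                   rbind(snap$ligand$features, snap$receptor$features))

  enc <- egm_encoder(psi_h = 9, n_layers = 3, hidden = 8, psi_prompt = 0,
                     seed = 5)
  for (k in grep("phi_m\\.|phi_mu\\.", names(enc$params), value = TRUE)) {
    enc$params[[k]] <- 0 * enc$params[[k]]
  }
  e <- egm_encode(enc, snap)
  expect_equal(e$coords, egmatch:::snapshot_coords(snap))
  expect_false(isTRUE(all.equal(
    e$features, rbind(snap$ligand$features, snap$receptor$features))))
})

test_that("cross attention is a proper softmax over neighbors", {
  tp <- egmatch:::tape_new(FALSE)
  # two receivers: one with inner products (0, ln 3), one with a single edge
  z <- egmatch:::tp_const(tp, matrix(c(0, log(3), 2.2), ncol = 1))
  a <- egmatch:::tp_value(tp, egmatch:::tp_group_softmax(tp, z, c(1, 1, 2), 2))
  expect_equal(as.vector(a), c(0.25, 0.75, 1), tolerance = 1e-9)

  set.seed(204)
  zr <- egmatch:::tp_const(tp, matrix(rnorm(12, 0, 5), ncol = 1))
  grp <- sample(1:4, 12, replace = TRUE)
  w <- as.vector(egmatch:::tp_value(
    tp, egmatch:::tp_group_softmax(tp, zr, grp, 4)))
  expect_true(all(w > 0 & w < 1 + 1e-12))
  sums <- tapply(w, grp, sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("equal neighbor features yield uniform attention and zero weight kills the message", {
  set.seed(205)
  # complex where every receptor atom shares one feature vector
  lig <- molecular_graph(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  rec <- molecular_graph(rep("O", 4),
                         rbind(c(2.5, 0, 0), c(0, 2.5, 0), c(0, 0, 2.5),
                               c(-2.5, 0, 0)))
  snap <- complex_snapshot(lig, rec)
  enc <- egm_encoder(psi_h = 9, n_layers = 1, hidden = 8, psi_prompt = 0,
                     seed = 11)
  # reproduce the layer-1 attention weights directly
  tp <- egmatch:::tape_new(FALSE)
  nested <- egmatch:::leaves_nest(egmatch:::params_leaves(tp, enc$params))
  edges <- egmatch:::snapshot_edge_index(snap)
  H <- egmatch:::tp_const(tp, rbind(snap$ligand$features,
                                    snap$receptor$features))
  dc <- edges$cross[, 1]; sc <- edges$cross[, 2]
  s1 <- enc$shapes$layers[[1]]
  q <- egmatch:::mlp_forward(tp, nested$layers$L1$phi_q, s1$phi_q,
                             egmatch:::tp_rows(tp, H, dc))
  k <- egmatch:::mlp_forward(tp, nested$layers$L1$phi_k, s1$phi_k,
                             egmatch:::tp_rows(tp, H, sc))
  a <- egmatch:::tp_value(tp, egmatch:::tp_group_softmax(
    tp, egmatch:::tp_rowsums(tp, egmatch:::tp_mul(tp, q, k)), dc, edges$n))
  # ligand atom 1 sees all-identical receptor features -> uniform weights
  deg1 <- sum(dc == 1)
  expect_gt(deg1, 1)
  expect_equal(as.vector(a[dc == 1]), rep(1 / deg1, deg1), tolerance = 1e-9)
})

test_that("a single coordinate update follows the weighted relative-position rule", {
  # one edge, w = 0.5, deg 1: x_i' = x_i + (x_i - x_j) * 0.5
  xi <- c(0, 0, 0); xj <- c(1, 0, 0)
  expect_equal(xi + (xi - xj) * 0.5, c(-0.5, 0, 0))
  # realized by the encoder: isolated atoms keep their coordinates
  set.seed(206)
  lone <- complex_snapshot(
    molecular_graph(c("C", "C"), rbind(c(0, 0, 0), c(50, 0, 0)),
                    intra_cutoff = 1),
    molecular_graph(c("O", "O"), rbind(c(100, 0, 0), c(150, 0, 0)),
                    intra_cutoff = 1))
  enc <- egm_encoder(psi_h = 9, n_layers = 2, hidden = 8, psi_prompt = 0,
                     seed = 2)
  e <- egm_encode(enc, lone)
  expect_equal(e$coords, egmatch:::snapshot_coords(lone))
})

test_that("sub-networks evaluate as plain two-layer perceptrons", {
  set.seed(207)
  blk <- egmatch:::mlp_init(3, 4, 2)
  x <- matrix(rnorm(6), 2, 3)
  tp <- egmatch:::tape_new(FALSE)
  ids <- egmatch:::leaves_nest(egmatch:::params_leaves(
    tp, egmatch:::params_flatten(list(g = blk))))
  got <- egmatch:::tp_value(tp, egmatch:::mlp_forward(tp, ids$g, blk,
                                                      egmatch:::tp_const(tp, x)))
  hand <- tanh(sweep(x %*% blk$W1, 2, blk$b1, "+")) %*% blk$W2
  hand <- sweep(hand, 2, blk$b2, "+")
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("the prompt changes features but preserves equivariance", {
  set.seed(208)
  enc <- egm_encoder(psi_h = 9, n_layers = 2, hidden = 8, psi_prompt = 6,
                     seed = 13)
  snap <- random_complex()
  pr <- rnorm(6, 0, 0.1)
  e1 <- egm_encode(enc, snap, prompt = pr)
  e0 <- egm_encode(enc, snap)
  expect_gt(max(abs(e1$features - e0$features)), 1e-8)
  R <- random_rotation(); tau <- rnorm(3)
  e2 <- egm_encode(enc, transform_snapshot(snap, R, tau), prompt = pr)
  expect_lt(max(abs(e2$features - e1$features)), 1e-5)
  expect_lt(max(abs(e2$coords - sweep(e1$coords %*% t(R), 2, tau, "+"))),
            1e-5)
  expect_error(egm_encode(enc, snap, prompt = rnorm(3)), "psi_prompt")
})
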