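# pre-training tasks: generation pairs, losses, ordering decode, joint step

make_toy_trajectory <- function(T_len = 10, n_lig = 3, n_rec = 6) {
  lig0 <- matrix(rnorm(3 * n_lig, 0, 1), n_lig, 3)
  rec0 <- matrix(rnorm(3 * n_rec, 0, 2.5), n_rec, 3)
  snaps <- lapply(seq_len(T_len), function(t) {
    complex_snapshot(
      molecular_graph(rep("C", n_lig), lig0 + 0.1 * t),
      molecular_graph(rep("O", n_rec), rec0),
      timestep = t)
  })
  trajectory(snaps, complex_id = "toy")
}

test_that("generation pairs index the right target frame", {
  set.seed(301)
  traj <- make_toy_trajectory(10)
  cfg <- egm_pretrain_config(sigma = 0, interval_set = 2L, steps = 1)
  for (rep in 1:5) {
    gp <- sample_generation_pair(traj, cfg)
    expect_equal(gp$dt, 2L)
    expect_lte(gp$t + gp$dt, 10L)
    expect_equal(gp$target,
                 egmatch:::snapshot_coords(traj$snapshots[[gp$t + gp$dt]]))
    # sigma = 0: source frames are clean
    expect_equal(egmatch:::snapshot_coords(gp$source),
                 egmatch:::snapshot_coords(traj$snapshots[[gp$t]]))
  }
  short <- make_toy_trajectory(3)
  expect_error(
    sample_generation_pair(short, egm_pretrain_config(interval_set = 9L)),
    "too short")
})

test_that("feasible intervals are drawn uniformly", {
  set.seed(302)
  traj <- make_toy_trajectory(10)
  cfg <- egm_pretrain_config(sigma = 0, interval_set = c(1L, 5L))
  dts <- replicate(10000, sample_generation_pair(traj, cfg)$dt)
  freq <- table(dts) / length(dts)
  expect_equal(as.vector(freq), c(0.5, 0.5), tolerance = 0.02)
})

test_that("generation loss has the unit identities and rigid invariance", {
  set.seed(303)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(generation_loss(x, x), 0)
  off <- sweep(x, 2, c(1, 0, 0), "+")
  expect_equal(generation_loss(off, x), 1.0)
  R <- random_rotation(); tau <- rnorm(3)
  pred <- x + matrix(rnorm(30, 0, 0.5), 10, 3)
  l1 <- generation_loss(pred, x)
  l2 <- generation_loss(sweep(pred %*% t(R), 2, tau, "+"),
                        sweep(x %*% t(R), 2, tau, "+"))
  expect_lt(abs(l1 - l2), 1e-8)
  expect_error(generation_loss(x, x[1:5, ]), "shape")
})

test_that("pairwise ordering probabilities are antisymmetric", {
  set.seed(304)
  clf <- order_classifier(psi_h = 9, hidden = 8, seed = 1)
  H_a <- rnorm(9); H_b <- rnorm(9)
  p_ab <- pairwise_order_prob(clf, H_a, H_b)
  p_ba <- pairwise_order_prob(clf, H_b, H_a)
  expect_lt(abs(p_ab + p_ba - 1), 1e-6)
  expect_equal(pairwise_order_prob(clf, H_a, H_a), 0.5, tolerance = 1e-9)
  # hand evaluation with a tiny known scorer
  clf2 <- order_classifier(psi_h = 1, hidden = 2, seed = 2)
  g <- function(a, b) {
    x <- matrix(c(a, b), 1, 2)
    h <- tanh(sweep(x %*% clf2$shapes$g$W1, 2, clf2$shapes$g$b1, "+"))
    as.vector(sweep(h %*% clf2$shapes$g$W2, 2, clf2$shapes$g$b2, "+"))
  }
  expect_equal(pairwise_order_prob(clf2, 0.3, -0.2),
               1 / (1 + exp(-(g(0.3, -0.2) - g(-0.2, 0.3)))),
               tolerance = 1e-9)
})

test_that("ordering loss identities and constraint count hold", {
  expect_lt(ordering_loss(rep(1, 10), rep(1, 10)), 1e-5)
  expect_equal(ordering_loss(rep(0.5, 6), c(1, 0, 1, 0, 1, 1)), log(2))
  expect_error(ordering_loss(c(0.5, 0.5), c(1)), "constraint")
  set.seed(305)
  traj <- make_toy_trajectory(8)
  os <- sample_ordering(traj, 5)
  expect_equal(nrow(os$constraints), 10L)  # n(n-1)/2
  expect_true(all(sort(os$true_order) == 1:5))
})

test_that("decode_order recovers consistent orders and matches exhaustive search", {
  # n = 2 next-snapshot case
  P2 <- matrix(c(0, 0.1, 0.9, 0), 2, 2)
  expect_equal(decode_order(P2), c(1L, 2L))
  # probabilities consistent with the permutation (3, 1, 4, 2)
  target <- c(3L, 1L, 4L, 2L)
  pos <- order(target)
  P <- matrix(0.5, 4, 4)
  for (a in 1:3) for (b in (a + 1):4) {
    p <- if (pos[a] < pos[b]) 0.85 else 0.15
    P[a, b] <- p; P[b, a] <- 1 - p
  }
  expect_equal(decode_order(P), target)
  expect_equal(order_score(decode_order(P), P),
               max(apply(all_perms(4), 1, order_score, P = P)))
  # cyclic triple: equals the best order under the coherence objective
  P3 <- matrix(0.5, 3, 3)
  P3[1, 2] <- 0.6; P3[2, 1] <- 0.4
  P3[2, 3] <- 0.6; P3[3, 2] <- 0.4
  P3[3, 1] <- 0.6; P3[1, 3] <- 0.4
  expect_equal(order_score(decode_order(P3), P3),
               max(apply(all_perms(3), 1, order_score, P = P3)))
  expect_error(decode_order(matrix(0.5, 1, 1)), "two items")
})

test_that("decode_order attains the exhaustive optimum on random tables", {
  set.seed(306)
  for (n in 2:5) {
    for (rep in 1:30) {
      P <- random_prob_table(n)
      best <- max(apply(all_perms(n), 1, order_score, P = P))
      expect_lt(abs(order_score(decode_order(P), P) - best), 1e-9)
    }
  }
})

test_that("task toggles shape the combined loss and gradients", {
  set.seed(307)
  traj <- make_toy_trajectory(8)
  # ordering off: combined loss equals the generation loss
  cfg <- egm_pretrain_config(steps = 2, n_layers = 1, hidden = 4,
                             psi_prompt = 2, interval_set = 1L,
                             use_ordering = FALSE)
  m <- egm_pretrain(traj, cfg, seed = 1)
  expect_equal(m$history$loss, m$history$generation)
  expect_true(all(is.na(m$history$ordering)))

  # lambda = 1: ordering is computed but its gradients are exactly zero
  cfg2 <- egm_pretrain_config(steps = 1, n_layers = 1, hidden = 4,
                              psi_prompt = 2, interval_set = 1L, lambda = 1)
  m2 <- egm_pretrain(traj, cfg2, seed = 2)
  flat <- egmatch:::joint_params(m2)
  set.seed(3)
  gp <- sample_generation_pair(traj, cfg2)
  os <- sample_ordering(traj, cfg2$n_order)
  tp <- egmatch:::tape_new(TRUE)
  built <- egmatch:::pretrain_batch_tape(tp, flat, m2, list(gp), list(os))
  grads <- egmatch:::leaves_grads(egmatch:::tape_backward(tp, built$loss),
                                  built$leaf_ids, flat)
  ord_keys <- grep("^ord\\.", names(grads), value = TRUE)
  expect_gt(length(ord_keys), 0)
  for (k in ord_keys) expect_true(all(grads[[k]] == 0))
  # the ordering loss itself is still evaluated
  expect_true(is.finite(egmatch:::tp_value(tp, built$ord)))

  # both tasks off is a configuration error
  expect_error(egm_pretrain_config(use_generation = FALSE,
                                   use_ordering = FALSE), "task")
})

test_that("the naive generative configuration disables noise and prompts", {
  cfg <- egm_pretrain_config(use_noise = FALSE, use_prompt = FALSE,
                             use_ordering = FALSE)
  expect_equal(cfg$sigma, 0)
  expect_equal(cfg$interval_set, 1L)
  expect_equal(cfg$psi_prompt, 0L)
  traj <- make_toy_trajectory(6)
  m <- egm_pretrain(traj, egm_pretrain_config(
    use_noise = FALSE, use_prompt = FALSE, use_ordering = FALSE,
    steps = 2, n_layers = 1, hidden = 4), seed = 4)
  expect_null(m$prompts)
  expect_null(m$order_clf)
})

test_that("zeroed coordinate nets reproduce the copy-input baseline exactly", {
  set.seed(308)
  traj <- make_toy_trajectory(6)
  enc <- egm_encoder(psi_h = 9, n_layers = 2, hidden = 4, psi_prompt = 0,
                     seed = 9)
  for (k in grep("phi_m\\.|phi_mu\\.", names(enc$params), value = TRUE)) {
    enc$params[[k]] <- 0 * enc$params[[k]]
  }
  cfg <- egm_pretrain_config(sigma = 0, interval_set = 1L, use_prompt = FALSE,
                             steps = 1)
  gp <- sample_generation_pair(traj, cfg)
  out <- egm_encode(enc, gp$source)
  copy_baseline <- generation_loss(egmatch:::snapshot_coords(gp$source),
                                   gp$target)
  expect_equal(generation_loss(out$coords, gp$target), copy_baseline)
})
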