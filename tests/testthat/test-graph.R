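# complex graph construction: cutoff rules, pocket, efficacy region,
# perturbation

test_that("intra edges follow the inclusive 4 A cutoff", {
  near <- molecular_graph(c("C", "C"), rbind(c(0, 0, 0), c(3.9, 0, 0)))
  expect_equal(sort_edges(near$intra_edges), rbind(c(1L, 2L), c(2L, 1L)))
  far <- molecular_graph(c("C", "C"), rbind(c(0, 0, 0), c(4.1, 0, 0)))
  expect_equal(nrow(far$intra_edges), 0L)
  at <- molecular_graph(c("C", "C"), rbind(c(0, 0, 0), c(4.0, 0, 0)))
  expect_equal(nrow(at$intra_edges), 2L)
})

test_that("edge set matches the exhaustive pairwise oracle and is symmetric", {
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(rnorm(60, 0, 3), 20, 3)
    g <- molecular_graph(rep("C", 20), x)
    expect_equal(sort_edges(g$intra_edges), sort_edges(brute_edges(x, 4)))
    # symmetry and no self edges
    e <- g$intra_edges
    expect_false(any(e[, 1] == e[, 2]))
    flipped <- e[, 2:1, drop = FALSE]
    expect_equal(sort_edges(e), sort_edges(flipped))
  }
})

test_that("graph construction validates its inputs", {
  expect_error(molecular_graph(character(0), matrix(0, 0, 3)), "atom")
  expect_error(molecular_graph("C", matrix(c(1, NA, 3), 1, 3)), "finite")
  expect_error(molecular_graph("C", matrix(0, 1, 3), intra_cutoff = -1),
               "positive")
})

test_that("atom features are one-hot plus electronegativity", {
  f <- atom_features(c("C", "O", "Cl", "Zn", "X"))
  expect_equal(dim(f), c(5L, length(egm_element_vocab()) + 1L))
  expect_equal(rowSums(f[, seq_along(egm_element_vocab())]), rep(1, 5))
  expect_equal(f[2, which(egm_element_vocab() == "O")], 1)
  expect_equal(f[3, which(egm_element_vocab() == "halogen")], 1)
  expect_equal(f[4, which(egm_element_vocab() == "metal")], 1)
  expect_equal(f[5, which(egm_element_vocab() == "other")], 1)
  expect_equal(f[1, ncol(f)], 2.55 / 4)  # carbon Pauling electronegativity
})

test_that("pocket extraction keeps atoms strictly inside 6 A and errors when empty", {
  lig <- molecular_graph("C", matrix(0, 1, 3))
  rec <- molecular_graph(c("C", "C", "C"),
                         rbind(c(5.9, 0, 0), c(6.1, 0, 0), c(2, 0, 0)))
  pocket <- extract_pocket(rec, lig)
  expect_equal(pocket$atom_ids, c(1L, 3L))
  far <- molecular_graph(c("C", "C"), rbind(c(7, 0, 0), c(9, 0, 0)))
  expect_error(extract_pocket(far, lig), "no pocket exists")
})

test_that("pocket extraction matches the brute-force minimum-distance filter and is idempotent", {
  set.seed(21)
  lig <- random_graph(4, spread = 1)
  rec <- random_graph(50, spread = 5)
  pocket <- extract_pocket(rec, lig, threshold = 6)
  dmin <- apply(egmatch:::cross_distances(rec$coords, lig$coords), 1, min)
  expect_equal(pocket$atom_ids, which(dmin < 6))
  again <- extract_pocket(pocket, lig, threshold = 6)
  expect_equal(again$atom_ids, pocket$atom_ids)
  expect_equal(again$coords, pocket$coords)
  expect_equal(sort_edges(again$intra_edges), sort_edges(pocket$intra_edges))
})

test_that("cross edges follow the cutoff and the brute-force oracle", {
  lig <- molecular_graph("C", matrix(0, 1, 3))
  rec <- molecular_graph(c("C", "C"), rbind(c(3, 0, 0), c(4.5, 0, 0)))
  ce <- build_cross_edges(lig, rec, 4)
  expect_equal(unname(ce), matrix(c(1L, 1L), 1, 2))
  none <- build_cross_edges(lig, molecular_graph("C", matrix(c(9, 0, 0), 1, 3)), 4)
  expect_equal(nrow(none), 0L)
  set.seed(31)
  lig <- random_graph(6, spread = 2)
  rec <- random_graph(15, spread = 3)
  ce <- build_cross_edges(lig, rec, 4)
  manual <- which(egmatch:::cross_distances(lig$coords, rec$coords) <= 4,
                  arr.ind = TRUE)
  expect_equal(sort_edges(unname(ce)), sort_edges(unname(manual)))
})

test_that("efficacy region applies the 5.5 A radius and rebuilds edges", {
  lig <- molecular_graph("C", matrix(0, 1, 3))
  rec <- molecular_graph(c("C", "C", "C"),
                         rbind(c(5.4, 0, 0), c(5.6, 0, 0), c(3, 0, 0)))
  snap <- complex_snapshot(lig, rec)
  region <- efficacy_region(snap)
  expect_equal(region$receptor$atom_ids, c(1L, 3L))
  # vacuous radius leaves the snapshot unchanged
  big <- efficacy_region(snap, radius = 100)
  expect_equal(big$receptor$coords, rec$coords)
  expect_equal(sort_edges(big$cross_edges), sort_edges(snap$cross_edges))
  expect_error(efficacy_region(complex_snapshot(
    lig, molecular_graph("C", matrix(c(8, 0, 0), 1, 3)))), "empty")
})

test_that("efficacy region matches the brute-force filter on random complexes", {
  set.seed(41)
  snap <- random_complex(5, 30)
  region <- efficacy_region(snap, radius = 5.5)
  dmin <- apply(egmatch:::cross_distances(snap$receptor$coords,
                                          snap$ligand$coords), 1, min)
  expect_equal(region$receptor$atom_ids, which(dmin < 5.5))
})

test_that("perturbation adds N(0, sigma^2) noise with frozen topology", {
  set.seed(51)
  snap <- random_complex()
  expect_identical(perturb_snapshot(snap, 0), snap)
  expect_error(perturb_snapshot(snap, -0.1), "sigma")
  noisy <- perturb_snapshot(snap, 0.3)
  expect_identical(noisy$ligand$intra_edges, snap$ligand$intra_edges)
  expect_identical(noisy$cross_edges, snap$cross_edges)
  expect_identical(noisy$ligand$features, snap$ligand$features)
  withf <- perturb_snapshot(snap, 0.3, perturb_features = TRUE)
  expect_false(identical(withf$ligand$features, snap$ligand$features))
})

test_that("mean perturbation displacement matches the 3-dof chi distribution", {
  set.seed(61)
  n <- 10000
  big <- complex_snapshot(
    molecular_graph(rep("C", n), matrix(runif(3 * n, -50, 50), n, 3),
                    intra_cutoff = 0.1),
    molecular_graph(c("C", "C"), rbind(c(100, 0, 0), c(101, 0, 0))))
  sigma <- 0.1
  noisy <- perturb_snapshot(big, sigma)
  disp <- sqrt(rowSums((noisy$ligand$coords - big$ligand$coords)^2))
  chi3_mean <- sigma * sqrt(2) * gamma(2) / gamma(1.5)  # E||N(0, s^2 I_3)||
  expect_lt(abs(mean(disp) - chi3_mean) / chi3_mean, 0.02)
})

test_that("edge construction is permutation-stable and rigid-transform invariant", {
  set.seed(71)
  x <- matrix(rnorm(36, 0, 3), 12, 3)
  g <- molecular_graph(rep("C", 12), x)
  perm <- sample(12)
  gp <- molecular_graph(rep("C", 12), x[perm, , drop = FALSE])
  mapped <- cbind(perm[gp$intra_edges[, 1]], perm[gp$intra_edges[, 2]])
  expect_equal(sort_edges(mapped), sort_edges(g$intra_edges))

  R <- random_rotation(); tau <- rnorm(3)
  xr <- sweep(x %*% t(R), 2, tau, "+")
  gr <- molecular_graph(rep("C", 12), xr)
  expect_equal(sort_edges(gr$intra_edges), sort_edges(g$intra_edges))

  lig <- random_graph(4, spread = 1.5)
  rec <- random_graph(10, spread = 3)
  ce <- build_cross_edges(lig, rec, 4)
  ligr <- molecular_graph(lig$elements, sweep(lig$coords %*% t(R), 2, tau, "+"))
  recr <- molecular_graph(rec$elements, sweep(rec$coords %*% t(R), 2, tau, "+"))
  expect_equal(sort_edges(unname(build_cross_edges(ligr, recr, 4))),
               sort_edges(unname(ce)))
})

test_that("trajectories validate timestep order and atom consistency", {
  set.seed(81)
  s1 <- random_complex()
  s2 <- s1; s2$timestep <- 2L
  expect_s3_class(trajectory(list(s1, s2)), "trajectory")
  expect_error(trajectory(list(s2, s1)), "increasing")
  s3 <- random_complex(n_lig = 6); s3$timestep <- 3L
  expect_error(trajectory(list(s1, s2, s3)), "atom count")
})
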