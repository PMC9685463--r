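# shared fixtures: small random complexes, rigid transforms, brute-force
# distance oracles

random_graph <- function(n, spread = 3, elements = c("C", "N", "O", "S"),
                         cutoff = 4) {
  molecular_graph(sample(elements, n, replace = TRUE),
                  matrix(rnorm(3 * n, 0, spread), n, 3),
                  intra_cutoff = cutoff)
}

random_complex <- function(n_lig = 5, n_rec = 12, cutoff = 4) {
  lig <- random_graph(n_lig, spread = 1.5)
  rec <- random_graph(n_rec, spread = 3)
  complex_snapshot(lig, rec, cross_cutoff = cutoff)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_snapshot <- function(snapshot, R, tau) {
  x <- egmatch:::snapshot_coords(snapshot) %*% t(R)
  x <- sweep(x, 2, tau, "+")
  egmatch:::set_snapshot_coords(snapshot, x)
}

# exhaustive O(n^2) pairwise-distance edge oracle
brute_edges <- function(coords, cutoff) {
  n <- nrow(coords)
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
      out <- rbind(out, c(i, j))
    }
  }
  out
}

sort_edges <- function(e) {
  if (nrow(e) == 0) return(e)
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[p], nrow(p)))
  }))
}

order_score <- function(ord, P) {
  s <- 0
  n <- length(ord)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    s <- s + log(max(P[ord[i], ord[j]], 1e-12))
  }
  s
}

kendall_tau_orders <- function(ord_a, ord_b) {
  cor(order(ord_a), order(ord_b), method = "kendall")
}

random_prob_table <- function(n) {
  P <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n)) {
    p <- runif(1)
    P[a, b] <- p
    P[b, a] <- 1 - p
  }
  P
}
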