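# Toy MD-like trajectory generator: a small ligand bound in a hemispherical
# pocket, propagated by overdamped Langevin dynamics on a harmonic energy.
# The binding-strength parameter kappa sets the curvature of the ligand
# tethers, so frame-to-frame ligand mobility decreases as kappa grows --
# the mechanism that ties synthetic affinity labels to observable motion.

#' Configuration for the synthetic trajectory simulator
#'
#' @param n_ligand,n_receptor atom counts (>= 2 each).
#' @param frames number of recorded frames T (>= 2).
#' @param kappa binding strength: harmonic curvature of the ligand tethers
#'   in 1/Angstrom^2 energy units (>= 0); larger kappa = stronger binding =
#'   less mobile ligand.
#' @param eta thermal kick standard deviation in Angstrom per integration
#'   substep.
#' @param bond_stiffness stiffness of the intra-ligand chain bonds.
#' @param receptor_stiffness fixed tether stiffness of pocket atoms.
#' @param step_size Langevin integration step.
#' @param substeps integration substeps between recorded frames.
#' @param start_offset initial rigid displacement of the ligand from its
#'   tether anchors, in Angstrom; a positive value yields a ligand that
#'   drifts back into the pocket over the trajectory.
#' @param pocket_radius radius of the receptor hemisphere shell.
#' @param clash minimum allowed ligand-receptor distance at generation.
#' @param intra_cutoff,cross_cutoff graph edge cutoffs in Angstrom.
#' @param frame_spacing time units per recorded frame (metadata).
#' @param seed optional integer; generation and dynamics are deterministic
#'   given the seed.
#' @return list of class `egm_synthetic_config`.
#' @export
egm_synthetic_config <- function(n_ligand = 6L, n_receptor = 24L,
                                 frames = 20L, kappa = 1, eta = 0.1,
                                 bond_stiffness = 5, receptor_stiffness = 5,
                                 step_size = 0.02, substeps = 20L,
                                 start_offset = 2, pocket_radius = 4.5,
                                 clash = 1.5, intra_cutoff = 4,
                                 cross_cutoff = 4, frame_spacing = 1,
                                 seed = NULL) {
  stopifnot(n_ligand >= 2L, n_receptor >= 2L, frames >= 2L,
            kappa >= 0, eta >= 0)
  structure(as.list(environment()), class = "egm_synthetic_config")
}

# raw geometry: anchors, elements and the ligand bond list
generate_geometry <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_l <- config$n_ligand
  n_r <- config$n_receptor
  for (attempt in 1:20) {
    jitter <- 0.3 * attempt / 10 + 0.27
    # receptor shell: unit directions folded onto the lower hemisphere
    u <- matrix(stats::rnorm(3L * n_r), n_r, 3L)
    u <- u / sqrt(rowSums(u^2))
    u[, 3L] <- -abs(u[, 3L])
    rec <- u * (config$pocket_radius + stats::rnorm(n_r, 0, jitter))
    # ligand: a fixed template conformation (bent zig-zag chain, bonds
    # ~1.5 A) shared by every complex -- like a real compound's equilibrium
    # geometry -- randomly rotated and lightly jittered at the pocket center
    idx <- seq_len(n_l)
    template <- cbind(1.2 * (idx - mean(idx)),
                      0.45 * (-1)^idx,
                      0.08 * (idx - mean(idx))^2)
    template <- sweep(template, 2L, colMeans(template))
    R <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
    lig <- template %*% t(R) +
      matrix(stats::rnorm(3L * n_l, 0, 0.05), n_l, 3L)
    if (min(cross_distances(lig, rec)) >= config$clash) {
      elements_l <- sample(c("C", "C", "C", "N", "O"), n_l, replace = TRUE)
      elements_r <- sample(c("C", "C", "N", "O", "S"), n_r, replace = TRUE)
      bonds <- cbind(seq_len(n_l - 1L), seq.int(2L, n_l))
      return(list(lig = lig, rec = rec, elements_l = elements_l,
                  elements_r = elements_r, bonds = bonds,
                  bond_len = sqrt(rowSums((lig[bonds[, 1L], , drop = FALSE] -
                                           lig[bonds[, 2L], , drop = FALSE])^2))))
    }
  }
  stop("could not place a clash-free complex; widen the pocket")
}

geometry_snapshot <- function(geo, config, lig_coords = NULL,
                              rec_coords = NULL, timestep = 0L) {
  lig <- molecular_graph(geo$elements_l,
                         if (is.null(lig_coords)) geo$lig else lig_coords,
                         intra_cutoff = config$intra_cutoff)
  rec <- molecular_graph(geo$elements_r,
                         if (is.null(rec_coords)) geo$rec else rec_coords,
                         intra_cutoff = config$intra_cutoff)
  complex_snapshot(lig, rec, cross_cutoff = config$cross_cutoff,
                   timestep = timestep)
}

#' Generate a single toy ligand-pocket complex
#'
#' Receptor atoms sit on a jittered hemispherical shell (the pocket);
#' ligand atoms form a short chain clustered at the pocket center. Edges
#' follow the package's distance-cutoff rules. Deterministic given
#' `config$seed`. Geometry is re-jittered (up to 20 attempts) if the
#' ligand-receptor clash constraint or cross-edge existence fails.
#'
#' @param config an [egm_synthetic_config()].
#' @return a `complex_snapshot`.
#' @export
generate_complex <- function(config) {
  geo <- generate_geometry(config)
  snap <- geometry_snapshot(geo, config)
  if (nrow(snap$cross_edges) == 0L) {
    stop("generated geometry has no cross edges; increase cross_cutoff ",
         "or shrink pocket_radius")
  }
  snap
}

#' Simulate an MD-like trajectory of a toy complex
#'
#' Overdamped Langevin dynamics on the harmonic energy
#' U = kappa * sum ||x_i - anchor_i||^2 (ligand tethers)
#'   + bond_stiffness * sum (bond length deviation)^2 (ligand chain),
#' with pocket atoms tethered at fixed `receptor_stiffness` and N(0, eta^2)
#' thermal kicks per integration substep. The ligand starts rigidly
#' displaced by `start_offset` Angstrom in a random direction and relaxes
#' back toward its anchors. All frames share one reference frame; graphs
#' are rebuilt per frame from the instantaneous coordinates.
#'
#' @param config an [egm_synthetic_config()].
#' @param complex_id identifier for the resulting trajectory.
#' @return a `trajectory` with `config$frames` snapshots.
#' @export
simulate_trajectory <- function(config, complex_id = "synthetic") {
  geo <- generate_geometry(config)
  n_l <- config$n_ligand
  anchors <- rbind(geo$lig, geo$rec)
  x <- anchors
  if (config$start_offset > 0) {
    d <- stats::rnorm(3L)
    x[seq_len(n_l), ] <- sweep(x[seq_len(n_l), , drop = FALSE], 2L,
                               config$start_offset * d / sqrt(sum(d^2)), "+")
  }
  stiff <- c(rep(config$kappa, n_l), rep(config$receptor_stiffness,
                                         nrow(geo$rec)))
  snaps <- vector("list", config$frames)
  for (f in seq_len(config$frames)) {
    snaps[[f]] <- geometry_snapshot(geo, config,
                                    lig_coords = x[seq_len(n_l), , drop = FALSE],
                                    rec_coords = x[-seq_len(n_l), , drop = FALSE],
                                    timestep = f)
    if (f == config$frames) break
    for (s in seq_len(config$substeps)) {
      grad <- 2 * stiff * (x - anchors)
      if (nrow(geo$bonds)) {
        i <- geo$bonds[, 1L]; j <- geo$bonds[, 2L]
        dvec <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
        len <- sqrt(rowSums(dvec^2))
        pull <- 2 * config$bond_stiffness * (len - geo$bond_len) / pmax(len, 1e-9)
        grad[i, ] <- grad[i, ] + dvec * pull
        grad[j, ] <- grad[j, ] - dvec * pull
      }
      x <- x - config$step_size * grad +
        matrix(stats::rnorm(length(x), 0, config$eta), nrow(x), 3L)
      if (any(abs(x) > 1e3)) {
        stop("dynamics diverged; reduce step_size or stiffness")
      }
    }
  }
  trajectory(snaps, complex_id = complex_id,
             frame_spacing = config$frame_spacing)
}

#' Affinity and efficacy labels from the binding-strength parameter
#'
#' pK = a * log10(kappa) + b + N(0, s^2); efficacy = 1 iff kappa exceeds
#' `threshold`. With the defaults, kappa of 0.1 / 1 / 10 maps to mean pK
#' of 3 / 5 / 7.
#'
#' @param config an [egm_synthetic_config()] (kappa must be > 0).
#' @param a,b,s label line slope, intercept and noise SD.
#' @param threshold efficacy cut on kappa.
#' @return list with numeric `pK` and integer `efficacy`.
#' @export
assign_labels <- function(config, a = 2, b = 5, s = 0.1, threshold = 1) {
  if (config$kappa <= 0) stop("labels need kappa > 0")
  list(pK = a * log10(config$kappa) + b + stats::rnorm(1L, 0, s),
       efficacy = as.integer(config$kappa > threshold))
}

#' Simulate a labelled dataset of toy complexes
#'
#' Draws `n` complexes with binding strengths cycled from `kappas`,
#' simulates a trajectory for each and attaches labels. Per-complex seeds
#' are derived deterministically from `seed`.
#'
#' @param n number of complexes.
#' @param kappas vector of binding-strength levels to cycle through.
#' @param config base [egm_synthetic_config()]; kappa and seed are
#'   overridden per complex.
#' @param seed integer master seed.
#' @return data.frame-like list of class `egm_dataset` with components
#'   `trajectories` (list), `labels` (data.frame complex_id, kappa, pK,
#'   efficacy).
#' @export
egm_simulate_dataset <- function(n, kappas = c(0.1, 1, 10),
                                 config = egm_synthetic_config(),
                                 seed = 1L) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  trajectories <- vector("list", n)
  labels <- data.frame(complex_id = sprintf("cpx%03d", seq_len(n)),
                       kappa = rep_len(kappas, n), pK = NA_real_,
                       efficacy = NA_integer_)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$kappa <- labels$kappa[i]
    cfg$seed <- sub_seeds[i]
    trajectories[[i]] <- simulate_trajectory(cfg, labels$complex_id[i])
    lab <- assign_labels(cfg)
    labels$pK[i] <- lab$pK
    labels$efficacy[i] <- lab$efficacy
  }
  structure(list(trajectories = trajectories, labels = labels),
            class = "egm_dataset")
}

#' @export
print.egm_dataset <- function(x, ...) {
  cat(sprintf("<egm_dataset> %d labelled trajectories (kappa levels: %s)\n",
              length(x$trajectories),
              paste(sort(unique(x$labels$kappa)), collapse = ", ")))
  invisible(x)
}
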