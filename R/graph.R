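# Atom-level graphs for protein-ligand complexes: ligand and receptor
# (pocket) graphs with distance-cutoff intra edges, cross-graph edges,
# pocket / efficacy-region extraction and noise perturbation.

# Pauling electronegativities; unknown elements fall back to 2.0
.electronegativity <- c(
  H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19,
  F = 3.98, Cl = 3.16, Br = 2.96, I = 2.66, Se = 2.55, B = 2.04,
  Si = 1.90, Na = 0.93, K = 0.82, Mg = 1.31, Ca = 1.00, Zn = 1.65,
  Fe = 1.83, Mn = 1.55, Cu = 1.90, Ni = 1.91, Co = 1.88
)

.halogens <- c("F", "Cl", "Br", "I", "At")
.metals <- c("Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Ni", "Co",
             "Li", "Al")

#' Default element vocabulary for atom features
#'
#' Atoms are one-hot encoded over these categories; halogens and metals are
#' pooled. The one-hot block is concatenated with the element's Pauling
#' electronegativity (scaled by 1/4 so all feature entries are O(1)),
#' giving invariant features of width `length(vocab) + 1`.
#'
#' @return character vector of category names.
#' @export
egm_element_vocab <- function() {
  c("C", "N", "O", "S", "P", "halogen", "metal", "other")
}

element_category <- function(elements, vocab = egm_element_vocab()) {
  cat <- ifelse(elements %in% vocab, elements,
         ifelse(elements %in% .halogens, "halogen",
         ifelse(elements %in% .metals, "metal", "other")))
  cat[!cat %in% vocab] <- "other"
  cat
}

#' Invariant atom features from element symbols
#'
#' @param elements character vector of element symbols.
#' @param vocab one-hot vocabulary (see [egm_element_vocab()]).
#' @return numeric matrix, one row per atom, width `length(vocab) + 1`.
#' @export
atom_features <- function(elements, vocab = egm_element_vocab()) {
  cat <- element_category(elements, vocab)
  onehot <- outer(cat, vocab, "==") * 1
  en <- .electronegativity[elements]
  en[is.na(en)] <- 2.0
  cbind(onehot, unname(en) / 4)
}

# all pairwise distances between row sets A (n x 3) and B (m x 3)
cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

symmetric_edges <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  d <- as.matrix(stats::dist(coords))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(integer(0), 0L, 2L))
  edges <- rbind(hit, hit[, 2:1, drop = FALSE])
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  edges
}

#' Build a molecular graph from elements and coordinates
#'
#' Atoms are nodes; intra-graph edges connect every atom pair whose
#' Euclidean distance is less than or equal to `intra_cutoff` (4 Angstrom by
#' default). The edge set is stored symmetrically (both ordered directions)
#' with no self edges.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param intra_cutoff edge distance cutoff in Angstrom (inclusive).
#' @param atom_ids optional integer identifiers carried through subsetting.
#' @param vocab one-hot element vocabulary.
#' @return an object of class `molecular_graph` with fields `atom_ids`,
#'   `elements`, `coords`, `features`, `intra_edges` (m x 2 integer matrix)
#'   and `intra_cutoff`.
#' @export
molecular_graph <- function(elements, coords, intra_cutoff = 4.0,
                            atom_ids = NULL, vocab = egm_element_vocab()) {
  coords <- as.matrix(coords)
  if (length(elements) == 0L) stop("molecular graph needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be an N x 3 matrix matching `elements`")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinate")
  if (!is.numeric(intra_cutoff) || intra_cutoff <= 0) {
    stop("intra_cutoff must be positive")
  }
  if (is.null(atom_ids)) atom_ids <- seq_along(elements)
  structure(
    list(atom_ids = as.integer(atom_ids),
         elements = as.character(elements),
         coords = unname(coords),
         features = atom_features(elements, vocab),
         intra_edges = symmetric_edges(coords, intra_cutoff),
         intra_cutoff = intra_cutoff),
    class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms (%s), %d directed intra edges (cutoff %.2f A)\n",
              length(x$elements),
              paste(utils::head(unique(x$elements), 6), collapse = ","),
              nrow(x$intra_edges), x$intra_cutoff))
  invisible(x)
}

# restrict a graph to a subset of atom positions (logical or integer index),
# re-restricting intra edges and preserving original atom ids
subset_graph <- function(graph, keep) {
  keep <- which(if (is.logical(keep)) keep else seq_along(graph$elements) %in% keep)
  if (length(keep) == 0L) stop("subset would remove every atom")
  map <- integer(length(graph$elements))
  map[keep] <- seq_along(keep)
  e <- graph$intra_edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  e[] <- map[e]
  structure(
    list(atom_ids = graph$atom_ids[keep],
         elements = graph$elements[keep],
         coords = graph$coords[keep, , drop = FALSE],
         features = graph$features[keep, , drop = FALSE],
         intra_edges = e,
         intra_cutoff = graph$intra_cutoff),
    class = "molecular_graph")
}

#' Extract the binding pocket from a receptor graph
#'
#' Keeps receptor atoms whose minimum distance to any ligand atom is
#' strictly shorter than `threshold` (6 Angstrom by default). Intra edges
#' are restricted to the surviving atoms; original atom identifiers are
#' preserved in `atom_ids`.
#'
#' @param receptor,ligand `molecular_graph` objects.
#' @param threshold pocket distance threshold in Angstrom (exclusive).
#' @return the pocket as a `molecular_graph`.
#' @export
extract_pocket <- function(receptor, ligand, threshold = 6.0) {
  stopifnot(inherits(receptor, "molecular_graph"),
            inherits(ligand, "molecular_graph"))
  if (threshold <= 0) stop("threshold must be positive")
  dmin <- apply(cross_distances(receptor$coords, ligand$coords), 1L, min)
  keep <- dmin < threshold
  if (!any(keep)) stop("no pocket exists: no receptor atom within ",
                       threshold, " A of the ligand")
  subset_graph(receptor, keep)
}

#' Cross-graph edges between a ligand and a receptor
#'
#' @param ligand,receptor `molecular_graph` objects.
#' @param cross_cutoff distance cutoff in Angstrom (inclusive).
#' @return integer m x 2 matrix of (ligand index, receptor index) pairs;
#'   possibly empty.
#' @export
build_cross_edges <- function(ligand, receptor, cross_cutoff = 4.0) {
  if (cross_cutoff <= 0) stop("cross_cutoff must be positive")
  d <- cross_distances(ligand$coords, receptor$coords)
  hit <- which(d <= cross_cutoff, arr.ind = TRUE)
  dimnames(hit) <- NULL
  storage.mode(hit) <- "integer"
  hit
}

#' Assemble a protein-ligand complex snapshot
#'
#' @param ligand,receptor `molecular_graph` objects (the receptor is
#'   typically a pocket from [extract_pocket()]).
#' @param cross_cutoff cutoff for ligand-receptor edges in Angstrom.
#' @param timestep integer frame index.
#' @return object of class `complex_snapshot` with fields `ligand`,
#'   `receptor`, `cross_edges`, `timestep`, `cross_cutoff`.
#' @export
complex_snapshot <- function(ligand, receptor, cross_cutoff = 4.0,
                             timestep = 0L) {
  stopifnot(inherits(ligand, "molecular_graph"),
            inherits(receptor, "molecular_graph"))
  structure(
    list(ligand = ligand, receptor = receptor,
         cross_edges = build_cross_edges(ligand, receptor, cross_cutoff),
         cross_cutoff = cross_cutoff,
         timestep = as.integer(timestep)),
    class = "complex_snapshot")
}

#' @export
print.complex_snapshot <- function(x, ...) {
  cat(sprintf("<complex_snapshot> t=%d: ligand %d atoms, receptor %d atoms, %d cross edges\n",
              x$timestep, length(x$ligand$elements),
              length(x$receptor$elements), nrow(x$cross_edges)))
  invisible(x)
}

n_atoms <- function(snapshot) {
  length(snapshot$ligand$elements) + length(snapshot$receptor$elements)
}

snapshot_coords <- function(snapshot) {
  rbind(snapshot$ligand$coords, snapshot$receptor$coords)
}

# replace coordinates of a snapshot (ligand rows first) without rebuilding
# edges
set_snapshot_coords <- function(snapshot, coords) {
  n_l <- length(snapshot$ligand$elements)
  snapshot$ligand$coords <- coords[seq_len(n_l), , drop = FALSE]
  snapshot$receptor$coords <- coords[-seq_len(n_l), , drop = FALSE]
  snapshot
}

#' Restrict a snapshot to the efficacy region around the ligand
#'
#' Keeps receptor atoms lying within `radius` (inclusive upper bound
#' excluded: strictly closer than the radius is kept, following the same
#' strict rule as the pocket) of any ligand atom, then rebuilds the
#' receptor intra edges and the cross edges on the subset.
#'
#' @param snapshot a `complex_snapshot`.
#' @param radius region radius in Angstrom (default 5.5).
#' @return a `complex_snapshot` restricted to the region.
#' @export
efficacy_region <- function(snapshot, radius = 5.5) {
  stopifnot(inherits(snapshot, "complex_snapshot"))
  if (radius <= 0) stop("radius must be positive")
  dmin <- apply(cross_distances(snapshot$receptor$coords,
                                snapshot$ligand$coords), 1L, min)
  keep <- dmin < radius
  if (!any(keep)) stop("efficacy region is empty at radius ", radius, " A")
  complex_snapshot(snapshot$ligand, subset_graph(snapshot$receptor, keep),
                   cross_cutoff = snapshot$cross_cutoff,
                   timestep = snapshot$timestep)
}

#' Perturb a snapshot with Gaussian coordinate noise
#'
#' Adds an independent N(0, sigma^2) increment to every coordinate
#' component of both ligand and receptor. Edges are *not* recomputed: the
#' graph topology stays frozen at the clean geometry so that denoising
#' targets and connectivity remain consistent. Features are perturbed with
#' the same per-entry noise only when `perturb_features` is TRUE. Uses the
#' current R RNG stream; call `set.seed()` for reproducibility.
#'
#' @param snapshot a `complex_snapshot`.
#' @param sigma noise standard deviation in Angstrom (>= 0).
#' @param perturb_features also add N(0, sigma^2) noise to the invariant
#'   features (default FALSE).
#' @return the perturbed `complex_snapshot`.
#' @export
perturb_snapshot <- function(snapshot, sigma, perturb_features = FALSE) {
  stopifnot(inherits(snapshot, "complex_snapshot"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(snapshot)
  x <- snapshot_coords(snapshot)
  x <- x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), 3L)
  out <- set_snapshot_coords(snapshot, x)
  if (isTRUE(perturb_features)) {
    for (part in c("ligand", "receptor")) {
      f <- out[[part]]$features
      out[[part]]$features <- f + matrix(stats::rnorm(length(f), 0, sigma),
                                         nrow(f), ncol(f))
    }
  }
  out
}

#' Time-ordered trajectory of complex snapshots
#'
#' @param snapshots list of `complex_snapshot` objects with strictly
#'   increasing timesteps and identical atom counts, ordering and features
#'   (only coordinates vary between frames).
#' @param complex_id identifier string.
#' @param frame_spacing time units per frame (metadata only).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(snapshots, complex_id = "complex",
                       frame_spacing = 1) {
  stopifnot(length(snapshots) >= 1L,
            all(vapply(snapshots, inherits, logical(1), "complex_snapshot")))
  ts <- vapply(snapshots, `[[`, integer(1), "timestep")
  if (any(diff(ts) <= 0)) stop("timesteps must be strictly increasing")
  counts <- vapply(snapshots, n_atoms, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("all snapshots must share the same atom count")
  }
  el1 <- c(snapshots[[1]]$ligand$elements, snapshots[[1]]$receptor$elements)
  for (s in snapshots[-1]) {
    if (!identical(c(s$ligand$elements, s$receptor$elements), el1)) {
      stop("all snapshots must share atom ordering and elements")
    }
  }
  structure(list(snapshots = snapshots, complex_id = complex_id,
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frames of %d atoms (spacing %g)\n",
              x$complex_id, length(x$snapshots), n_atoms(x$snapshots[[1]]),
              x$frame_spacing))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$snapshots)
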