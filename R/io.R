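# Trajectory serialization: multi-MODEL PDB (via bio3d) and a compact
# plain-text columnar format, plus label tables. Ligand atoms are written
# as chain L and receptor atoms as chain R; on ingest the ligand is
# identified by HETATM records or by chain.

#' Write a trajectory to disk
#'
#' `format = "pdb"` writes one MODEL per frame with the ligand on chain L
#' (HETATM records) and the receptor on chain R; coordinates keep PDB's
#' three-decimal precision. `format = "native"` writes the package's
#' plain-text columnar schema:
#' \preformatted{
#' #egmtraj 1
#' id <complex_id>
#' n_ligand <N> n_receptor <M> frames <T> spacing <dt>
#' elements <N+M element symbols>
#' frame <t>
#' <x> <y> <z>          (N + M lines, ligand atoms first)
#' ...repeated per frame
#' }
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @param format "pdb" or "native" (default chosen from the extension:
#'   .pdb versus anything else).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = if (grepl("\\.pdb$", path)) "pdb"
                                      else "native") {
  stopifnot(inherits(traj, "trajectory"))
  s1 <- traj$snapshots[[1L]]
  n_l <- length(s1$ligand$elements)
  n_r <- length(s1$receptor$elements)
  elements <- c(s1$ligand$elements, s1$receptor$elements)
  if (format == "pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_along(traj$snapshots)) {
      x <- snapshot_coords(traj$snapshots[[f]])
      writeLines(sprintf("MODEL     %4d", f), con)
      for (i in seq_len(n_l + n_r)) {
        rec <- if (i <= n_l) "HETATM" else "ATOM  "
        chain <- if (i <= n_l) "L" else "R"
        resid <- if (i <= n_l) "LIG" else "REC"
        writeLines(sprintf(
          "%s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, i, substr(elements[i], 1, 4), resid, chain,
          if (i <= n_l) 1L else i - n_l, x[i, 1L], x[i, 2L], x[i, 3L],
          elements[i]), con)
      }
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    lines <- c("#egmtraj 1",
               paste("id", traj$complex_id),
               sprintf("n_ligand %d n_receptor %d frames %d spacing %g",
                       n_l, n_r, length(traj$snapshots), traj$frame_spacing),
               paste(c("elements", elements), collapse = " "))
    for (f in seq_along(traj$snapshots)) {
      x <- snapshot_coords(traj$snapshots[[f]])
      lines <- c(lines, paste("frame", traj$snapshots[[f]]$timestep),
                 sprintf("%.6f %.6f %.6f", x[, 1L], x[, 2L], x[, 3L]))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

# Kabsch least-squares superposition of `x` onto `ref` using the rows in
# `fit_idx`; returns the transformed full coordinate matrix
superpose_coords <- function(x, ref, fit_idx) {
  xa <- x[fit_idx, , drop = FALSE]
  ra <- ref[fit_idx, , drop = FALSE]
  cx <- colMeans(xa)
  cr <- colMeans(ra)
  s <- svd(t(sweep(xa, 2L, cx)) %*% sweep(ra, 2L, cr))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(x, 2L, cx) %*% t(R), 2L, cr, "+")
}

#' Read a trajectory from disk
#'
#' Accepts multi-MODEL (or single-model) PDB files and the native format
#' written by [write_trajectory()]. Ligand atoms are those with HETATM
#' records or on `ligand_chain`; everything else is receptor. Hydrogens
#' are dropped by default. When `pocket_threshold` is non-NULL the
#' receptor is restricted to the binding pocket (minimum ligand distance
#' strictly below the threshold, evaluated on frame 1) before graphs are
#' built. `superpose = TRUE` applies a least-squares superposition of the
#' receptor atoms of every frame onto frame 1, for trajectories not
#' expressed in one common reference frame.
#'
#' @param path input file.
#' @param ligand_chain chain identifier treated as ligand in PDB input.
#' @param drop_hydrogens drop H atoms on ingest.
#' @param pocket_threshold pocket rule threshold in Angstrom, or NULL to
#'   keep the full receptor.
#' @param superpose align receptor atoms of each frame to frame 1.
#' @param intra_cutoff,cross_cutoff graph construction cutoffs.
#' @param frame_spacing time units per frame (metadata).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, ligand_chain = "L", drop_hydrogens = TRUE,
                            pocket_threshold = NULL, superpose = FALSE,
                            intra_cutoff = 4, cross_cutoff = 4,
                            frame_spacing = 1) {
  if (grepl("\\.pdb$", path)) {
    # bio3d warns (rather than errors) on inconsistent MODEL blocks; the
    # atom-count check below turns that case into a format error
    pdb <- tryCatch(suppressWarnings(
                      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
                    error = function(e) {
                      stop("PDB format error: ", conditionMessage(e))
                    })
    elements <- pdb$atom$elesy
    blank <- is.na(elements) | elements == ""
    elements[blank] <- substr(trimws(pdb$atom$elety[blank]), 1L, 1L)
    is_lig <- pdb$atom$type == "HETATM" | pdb$atom$chain %in% ligand_chain
    keep <- rep(TRUE, length(elements))
    if (drop_hydrogens) keep <- toupper(elements) != "H"
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * length(elements)) {
      stop("format error: MODEL atom counts are inconsistent")
    }
    frames <- lapply(seq_len(nrow(xyz)), function(f) {
      matrix(xyz[f, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    })
    elements <- elements[keep]
    is_lig <- is_lig[keep]
    if (!any(is_lig)) stop("ligand selector matched no atoms")
    if (all(is_lig)) stop("ligand selector matched every atom")
    id <- sub("\\.pdb$", "", basename(path))
  } else {
    lines <- readLines(path)
    if (!startsWith(lines[1L], "#egmtraj")) {
      stop("format error: missing native trajectory header")
    }
    id <- strsplit(lines[2L], " ")[[1L]][2L]
    hdr <- as.numeric(strsplit(lines[3L], " ")[[1L]][c(2L, 4L, 6L, 8L)])
    n_l <- hdr[1L]; n_r <- hdr[2L]; n_f <- hdr[3L]
    frame_spacing <- hdr[4L]
    elements <- strsplit(lines[4L], " ")[[1L]][-1L]
    n <- n_l + n_r
    frames <- vector("list", n_f)
    ts <- integer(n_f)
    pos <- 5L
    for (f in seq_len(n_f)) {
      ts[f] <- as.integer(strsplit(lines[pos], " ")[[1L]][2L])
      block <- lines[(pos + 1L):(pos + n)]
      frames[[f]] <- matrix(scan(text = block, quiet = TRUE), ncol = 3L,
                            byrow = TRUE)
      pos <- pos + n + 1L
    }
    is_lig <- seq_len(n) <= n_l
    if (drop_hydrogens) {
      keep <- toupper(elements) != "H"
      frames <- lapply(frames, function(x) x[keep, , drop = FALSE])
      elements <- elements[keep]
      is_lig <- is_lig[keep]
    }
  }

  if (superpose && length(frames) > 1L) {
    ref <- frames[[1L]]
    rec_idx <- which(!is_lig)
    frames[-1L] <- lapply(frames[-1L], superpose_coords, ref = ref,
                          fit_idx = rec_idx)
  }

  pocket_keep <- NULL
  if (!is.null(pocket_threshold)) {
    d <- cross_distances(frames[[1L]][!is_lig, , drop = FALSE],
                         frames[[1L]][is_lig, , drop = FALSE])
    pk <- apply(d, 1L, min) < pocket_threshold
    if (!any(pk)) stop("no pocket exists: no receptor atom within ",
                       pocket_threshold, " A of the ligand")
    pocket_keep <- pk
  }

  snaps <- lapply(seq_along(frames), function(f) {
    x <- frames[[f]]
    lig <- molecular_graph(elements[is_lig], x[is_lig, , drop = FALSE],
                           intra_cutoff = intra_cutoff)
    rx <- x[!is_lig, , drop = FALSE]
    re <- elements[!is_lig]
    if (!is.null(pocket_keep)) {
      rx <- rx[pocket_keep, , drop = FALSE]
      re <- re[pocket_keep]
    }
    rec <- molecular_graph(re, rx, intra_cutoff = intra_cutoff,
                           atom_ids = if (is.null(pocket_keep)) NULL
                                      else which(pocket_keep))
    complex_snapshot(lig, rec, cross_cutoff = cross_cutoff, timestep = f)
  })
  trajectory(snaps, complex_id = id, frame_spacing = frame_spacing)
}

#' Write / read a label table
#'
#' Plain CSV with columns complex_id, task, value.
#'
#' @param labels data.frame with columns complex_id, task, value.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("complex_id", "task", "value") %in% names(labels)))
  utils::write.csv(labels[, c("complex_id", "task", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry an explicit schema version and the full `egm_model`
#' state (encoder, prompt table, ordering classifier, configuration).
#'
#' @param model an `egm_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "egm_model"))
  saveRDS(list(schema = "egm-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop("checkpoint not found at '", path,
         "'; run the pretrain step first or point `checkpoint` at one")
  }
  obj <- readRDS(path)
  if (!identical(obj$schema, "egm-checkpoint-1")) {
    stop("unrecognized checkpoint schema")
  }
  obj$model
}
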