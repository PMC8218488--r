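new_cluster_assignment <- function(labels, source) {
  structure(list(labels = as.integer(labels), source = source),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- sum(unique(x$labels) >= 0L)
  cat("<cluster_assignment> ", length(x$labels), " frames, ", k, " clusters, ",
      sum(x$labels == -1L), " noise (source: ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Cluster latent embeddings with HDBSCAN
#'
#' Runs [hdbscan()] over the per-frame latent mean vectors of an embedding.
#' Every returned cluster has at least `min_cluster_size` members; degenerate
#' input (fewer frames than `min_cluster_size`) yields all noise rather than
#' an error.
#'
#' @param embedding A `latent_embedding` (from [train_cvae()]) or a numeric
#'   matrix with one row per frame.
#' @param min_cluster_size Minimum cluster size (default 50 frames).
#' @param allow_single_cluster Passed to [hdbscan()].
#' @return A `cluster_assignment` with source `"latent"`.
#' @export
cluster_latent <- function(embedding, min_cluster_size = 50,
                           allow_single_cluster = TRUE) {
  z <- if (inherits(embedding, "latent_embedding")) embedding$z else as.matrix(embedding)
  labels <- hdbscan(z, min_cluster_size = min_cluster_size,
                    allow_single_cluster = allow_single_cluster)
  new_cluster_assignment(labels, "latent")
}

#' Quality-threshold RMSD clustering of binding modes
#'
#' The whole-molecule reference clustering: frames are first superposed on the
#' protein atoms by a least-squares rigid-body fit to frame 1, then the
#' pairwise ligand-atom RMSD matrix is computed without further fitting
#' (ligand RMSD measures how much the binding pose moved once the protein
#' frame of reference is fixed). Greedy quality-threshold clustering follows:
#' repeatedly take the frame with the most neighbors within `cutoff`
#' (lowest frame index on ties), assign that neighborhood as one cluster,
#' remove it, and repeat. Frames left over once `max_clusters` clusters have
#' been formed are labeled noise (-1).
#'
#' @param traj A `md_trajectory`.
#' @param cutoff RMSD cutoff in Angstrom (default 2.0).
#' @param max_clusters Cap on the number of clusters (default unlimited).
#' @return A `cluster_assignment` with source `"rmsd_reference"`.
#' @export
qt_rmsd_cluster <- function(traj, cutoff = 2.0, max_clusters = Inf) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff >= 0)
  if (length(traj$protein) == 0L || length(traj$ligand) == 0L) {
    stop("protein and ligand selections must be non-empty", call. = FALSE)
  }
  T_ <- n_frames(traj)
  pidx <- bio3d::atom2xyz(traj$protein)
  xyz <- traj$xyz
  if (T_ > 1L) {
    xyz <- bio3d::fit.xyz(fixed = traj$xyz[1L, ], mobile = traj$xyz,
                          fixed.inds = pidx, mobile.inds = pidx)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = T_)
  } else {
    xyz <- matrix(xyz, nrow = 1L)
  }
  D <- ligand_rmsd_matrix(xyz, traj$ligand)
  qt_cluster_matrix(D, cutoff, max_clusters)
}

# T x T ligand RMSD matrix from fitted coordinates (Gram-matrix identity).
ligand_rmsd_matrix <- function(xyz, ligand) {
  L <- xyz[, bio3d::atom2xyz(ligand), drop = FALSE]    # T x 3N
  nlig <- length(ligand)
  sq <- rowSums(L^2)
  G <- tcrossprod(L)
  d2 <- (outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) - 2 * G) / nlig
  d2[d2 < 0] <- 0
  diag(d2) <- 0                       # exact, despite Gram-identity rounding
  sqrt(d2)
}

# Greedy QT clustering of a precomputed distance matrix.
qt_cluster_matrix <- function(D, cutoff, max_clusters = Inf) {
  T_ <- nrow(D)
  labels <- rep(-1L, T_)
  remaining <- rep(TRUE, T_)
  neighbors <- D <= cutoff + 1e-9
  k <- 0L
  while (any(remaining) && k < max_clusters) {
    counts <- colSums(neighbors & remaining)
    counts[!remaining] <- -1L
    center <- which.max(counts)              # lowest index wins ties
    members <- union(center, which(neighbors[, center] & remaining))
    labels[members] <- k
    remaining[members] <- FALSE
    k <- k + 1L
  }
  new_cluster_assignment(labels, "rmsd_reference")
}

#' Per-frame cluster-size series from a cluster assignment
#'
#' `sizes[t]` is the number of frames sharing frame t's cluster label. Noise
#' frames get size 1: an unclustered frame is its own transient state, and a
#' singleton is the honest size of an unstable snapshot (0 would zero out
#' cosine terms asymmetrically).
#'
#' @param assign A `cluster_assignment` or integer label vector (-1 = noise).
#' @param identity `"subtype"` or `"molecule"` tag carried on the result.
#' @return Object of class `cluster_size_series`: list with integer `sizes`
#'   and `identity`.
#' @export
size_series <- function(assign, identity = "molecule") {
  labels <- if (inherits(assign, "cluster_assignment")) assign$labels else as.integer(assign)
  sizes <- rep(1L, length(labels))
  pos <- labels >= 0L
  if (any(pos)) {
    tab <- table(labels[pos])
    sizes[pos] <- as.integer(tab[as.character(labels[pos])])
  }
  structure(list(sizes = sizes, identity = identity), class = "cluster_size_series")
}

#' @export
print.cluster_size_series <- function(x, ...) {
  cat("<cluster_size_series> (", x$identity, ") T=", length(x$sizes),
      ", largest=", max(x$sizes), "\n", sep = "")
  invisible(x)
}

#' Is the dominant binding mode stable?
#'
#' A binding mode counts as stable when the largest cluster's total membership
#' time exceeds `min_persist_ns` (strictly longer; a cluster persisting for
#' exactly the threshold is not stable). Total membership time is used, i.e.
#' member count times the snapshot spacing.
#'
#' @param series A `cluster_size_series` (or a `cluster_assignment`).
#' @param frame_interval_ps Snapshot spacing in ps (> 0).
#' @param min_persist_ns Persistence threshold in ns (default 50).
#' @return Logical flag.
#' @export
is_stable <- function(series, frame_interval_ps = 20, min_persist_ns = 50) {
  stopifnot(frame_interval_ps > 0)
  sizes <- if (inherits(series, "cluster_assignment")) size_series(series)$sizes
           else as_sizes(series)
  max(sizes) * frame_interval_ps / 1000 > min_persist_ns
}

#' Read/write cluster assignments as two-column CSV
#'
#' The on-disk format is `frame,label` with 1-based frames and -1 for noise;
#' external reference clusterings are accepted in the same format.
#'
#' @param assign A `cluster_assignment`.
#' @param path CSV path.
#' @export
write_assignment <- function(assign, path) {
  utils::write.csv(
    data.frame(frame = seq_along(assign$labels), label = assign$labels),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "label") %in% names(df)))
  df <- df[order(df$frame), ]
  new_cluster_assignment(df$label, "external")
}
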