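#' Compute the binary ligand-protein contact series of a trajectory
#'
#' For every frame t, `values[t, i, j] = 1` iff the distance between ligand
#' atom i and protein atom j is at or below `cutoff` (closed comparison, so a
#' pair at exactly the cutoff counts as a contact and results are deterministic
#' on exact fixtures). Hydrogens are included whenever the selections include
#' them.
#'
#' @param traj A `md_trajectory`.
#' @param cutoff Contact distance in Angstrom (> 0). Default 4.5, a
#'   conventional heavy-contact distance for atom-pair contact maps.
#' @return Object of class `contact_series`: list with `values`
#'   (T x N x M integer array of 0/1), `cutoff`, `ligand_labels`,
#'   `protein_labels`, `frame_interval_ps`.
#' @export
compute_contact_series <- function(traj, cutoff = 4.5) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0)
  T_ <- n_frames(traj)
  N <- length(traj$ligand)
  M <- length(traj$protein)
  li <- as.vector(rbind(3 * traj$ligand - 2, 3 * traj$ligand - 1, 3 * traj$ligand))
  pi_ <- as.vector(rbind(3 * traj$protein - 2, 3 * traj$protein - 1, 3 * traj$protein))
  vals <- array(0L, dim = c(T_, N, M))
  cut2 <- cutoff^2
  for (t in seq_len(T_)) {
    L <- matrix(traj$xyz[t, li], ncol = 3, byrow = TRUE)   # N x 3
    P <- matrix(traj$xyz[t, pi_], ncol = 3, byrow = TRUE)  # M x 3
    d2 <- outer(rowSums(L^2), rowSums(P^2), "+") - 2 * tcrossprod(L, P)
    vals[t, , ] <- (d2 <= cut2 + 1e-9) * 1L                # closed boundary
  }
  lig_lab <- paste0(traj$atoms$name[traj$ligand], "_", traj$ligand)
  pro_lab <- paste0(traj$atoms$name[traj$protein], "_", traj$protein)
  new_contact_series(vals, cutoff, lig_lab, pro_lab, traj$frame_interval_ps)
}

new_contact_series <- function(values, cutoff, ligand_labels = NULL,
                               protein_labels = NULL, frame_interval_ps = 20) {
  stopifnot(length(dim(values)) == 3L, all(values %in% c(0L, 1L)))
  structure(list(values = values, cutoff = cutoff,
                 ligand_labels = ligand_labels, protein_labels = protein_labels,
                 frame_interval_ps = frame_interval_ps),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<contact_series> T=", d[1], ", N=", d[2], ", M=", d[3],
      ", cutoff=", x$cutoff, " A, density=",
      signif(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Aggregate a contact series over the atoms of one subtype
#'
#' Collapses the ligand-atom axis to the single row of one atom subtype by
#' logical OR: the subtype is "in contact" with protein atom j at frame t iff
#' any of its member atoms is. OR keeps the series binary, which the
#' cross-entropy reconstruction loss of the autoencoder requires.
#'
#' @param contacts A `contact_series` with N ligand rows.
#' @param atom_to_subtype Integer vector of length N mapping each ligand atom
#'   (row) to its subtype id.
#' @param subtype_id Subtype to extract; must occur in `atom_to_subtype`.
#' @return A `contact_series` with dimensions T x 1 x M.
#' @export
aggregate_by_subtype <- function(contacts, atom_to_subtype, subtype_id) {
  stopifnot(inherits(contacts, "contact_series"))
  d <- dim(contacts$values)
  stopifnot(length(atom_to_subtype) == d[2])
  rows <- which(atom_to_subtype == subtype_id)
  if (length(rows) == 0L) {
    stop("subtype_id ", subtype_id, " has no ligand atoms in this mapping", call. = FALSE)
  }
  sub <- contacts$values[, rows, , drop = FALSE]
  agg <- apply(sub, c(1, 3), max)                       # T x M
  vals <- array(as.integer(agg), dim = c(d[1], 1L, d[3]))
  new_contact_series(vals, contacts$cutoff,
                     ligand_labels = paste0("subtype_", subtype_id),
                     protein_labels = contacts$protein_labels,
                     frame_interval_ps = contacts$frame_interval_ps)
}

#' Write / read a contact series (binary array container + JSON sidecar)
#'
#' The array is stored as a serialized R object; labels, cutoff and frame
#' interval go to a human-readable JSON sidecar next to it.
#'
#' @param contacts A `contact_series`.
#' @param path Output path for the array container; the sidecar is
#'   `<path>.json`.
#' @export
write_contact_series <- function(contacts, path) {
  stopifnot(inherits(contacts, "contact_series"))
  saveRDS(contacts$values, path, compress = "gzip")
  meta <- list(cutoff = contacts$cutoff,
               frame_interval_ps = contacts$frame_interval_ps,
               ligand_labels = contacts$ligand_labels,
               protein_labels = contacts$protein_labels,
               dim = dim(contacts$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contact_series
#' @export
read_contact_series <- function(path) {
  vals <- readRDS(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_contact_series(array(as.integer(vals), dim = meta$dim), meta$cutoff,
                     meta$ligand_labels, meta$protein_labels,
                     meta$frame_interval_ps)
}
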