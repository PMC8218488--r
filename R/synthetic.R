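#' Specification for a synthetic contact system with planted ground truth
#'
#' Describes a ligand whose atoms are grouped into subtype blocks with planted
#' temporal behavior:
#' \itemize{
#'   \item `stable` — the block keeps one fixed random contact fingerprint;
#'     each cell is independently corrupted at `noise` per frame (a stably
#'     bound moiety keeps its contact pattern, with rare transient contacts).
#'   \item `flicker` — each cell flips its state relative to the previous
#'     frame with probability `rate`, a per-cell random walk over patterns.
#'     Note that this drift is temporally continuous: its latent embedding is
#'     a connected filament that density clustering cannot fragment, so it is
#'     not a usable "planted unstable" block (see the methods vignette).
#'   \item `intermittent` — the planted-unstable behavior: a two-state
#'     detach/attach process. Detached stretches have no contacts; each
#'     attachment episode draws a fresh random fingerprint at `density` and
#'     holds it; state switches each frame with probability `rate` (mean
#'     episode length 1/`rate` frames). This is the contact signature of a
#'     moiety that repeatedly loses and regains transient contact patterns,
#'     and it fragments into the many small clusters expected of an unstable
#'     moiety.
#'   \item `switching` — the block alternates between two fixed fingerprints
#'     on a regular schedule (`switch_every` frames), emulating a discrete
#'     binding-mode change that is visible in the whole-molecule reference.
#' }
#'
#' @param T_ Number of frames (default 1000).
#' @param M Number of protein atoms (default 128; must satisfy the
#'   autoencoder's minimum length, see [build_cvae()]).
#' @param blocks Data frame with columns `subtype_id`, `n_atoms`, `behavior`
#'   (`"stable"`, `"flicker"`, `"intermittent"` or `"switching"`), `density`,
#'   `rate` (noise / flip / switching rate per frame; ignored for switching).
#'   Default: four stable blocks (noise 5e-4) and one planted intermittent
#'   block (rate 0.02, ~1 ns episodes at 20 ps/frame) of 2 atoms each,
#'   density 0.3.
#' @param switch_every Frames between switching-block pattern changes.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(T_ = 1000, M = 128, blocks = NULL,
                           switch_every = 250, seed = 1) {
  if (is.null(blocks)) {
    blocks <- data.frame(
      subtype_id = 0:4,
      n_atoms = 2L,
      behavior = c("stable", "stable", "intermittent", "stable", "stable"),
      density = 0.3,
      rate = c(5e-4, 5e-4, 0.02, 5e-4, 5e-4)
    )
  }
  stopifnot(T_ >= 1, M >= 1,
            all(blocks$behavior %in% c("stable", "flicker", "intermittent", "switching")),
            all(blocks$density >= 0 & blocks$density <= 1),
            all(blocks$rate >= 0 & blocks$rate <= 1),
            all(blocks$n_atoms >= 1))
  structure(list(T_ = as.integer(T_), M = as.integer(M), blocks = blocks,
                 switch_every = as.integer(switch_every), seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic contact system with planted ground truth
#'
#' Draws a T x N x M binary contact series according to a [synthetic_spec()],
#' together with the ground truth needed to test every pipeline stage: the
#' atom-to-subtype map, the planted malicious subtype ids (the non-stable
#' blocks), and a whole-molecule reference assignment labeling frames by
#' global regime (the combination of active switching-block patterns; with no
#' switching blocks all frames share regime 0).
#'
#' @param spec A `synthetic_spec`.
#' @return List: `contacts` (a `contact_series`), `atom_to_subtype` (integer
#'   vector of length N), `reference` (a `cluster_assignment`, source
#'   `"external"`), `malicious_subtypes` (integer vector), `spec`.
#' @export
generate_contact_system <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  T_ <- spec$T_; M <- spec$M
  blocks <- spec$blocks
  N <- sum(blocks$n_atoms)
  vals <- array(0L, dim = c(T_, N, M))
  atom_to_subtype <- rep(blocks$subtype_id, blocks$n_atoms)
  regime_key <- rep(0L, T_)
  row0 <- 0L
  for (b in seq_len(nrow(blocks))) {
    nb <- blocks$n_atoms[b]
    dens <- blocks$density[b]
    rate <- blocks$rate[b]
    rows <- row0 + seq_len(nb)
    if (blocks$behavior[b] == "stable") {
      base <- matrix(stats::rbinom(nb * M, 1L, dens), nb, M)
      for (t in seq_len(T_)) {
        noise <- matrix(stats::rbinom(nb * M, 1L, rate), nb, M)
        vals[t, rows, ] <- xor(base, noise) * 1L
      }
    } else if (blocks$behavior[b] == "flicker") {
      cur <- matrix(stats::rbinom(nb * M, 1L, dens), nb, M)
      vals[1L, rows, ] <- cur
      for (t in seq_len(T_)[-1L]) {
        flips <- matrix(stats::rbinom(nb * M, 1L, rate), nb, M)
        cur <- xor(cur, flips) * 1L
        vals[t, rows, ] <- cur
      }
    } else if (blocks$behavior[b] == "intermittent") {
      attached <- FALSE
      pat <- matrix(0L, nb, M)
      for (t in seq_len(T_)) {
        if (stats::runif(1) < rate) {
          attached <- !attached
          if (attached) pat <- matrix(stats::rbinom(nb * M, 1L, dens), nb, M)
        }
        vals[t, rows, ] <- if (attached) pat else matrix(0L, nb, M)
      }
    } else {                                  # switching
      pat <- list(matrix(stats::rbinom(nb * M, 1L, dens), nb, M),
                  matrix(stats::rbinom(nb * M, 1L, dens), nb, M))
      phase <- ((seq_len(T_) - 1L) %/% spec$switch_every) %% 2L
      for (t in seq_len(T_)) vals[t, rows, ] <- pat[[phase[t] + 1L]]
      regime_key <- regime_key * 2L + phase
    }
    row0 <- row0 + nb
  }
  regimes <- match(regime_key, unique(regime_key)) - 1L
  contacts <- new_contact_series(vals, cutoff = NA_real_,
                                 ligand_labels = paste0("atom_", seq_len(N)),
                                 protein_labels = paste0("p", seq_len(M)))
  list(contacts = contacts,
       atom_to_subtype = atom_to_subtype,
       reference = new_cluster_assignment(regimes, "external"),
       malicious_subtypes = blocks$subtype_id[blocks$behavior != "stable"],
       spec = spec)
}

#' Write a toy trajectory (multi-model PDB) with known pose structure
#'
#' Builds a ~12-atom rigid ligand next to a pseudo-protein helix of ~120
#' atoms and writes topology and coordinates as text PDB files the loader
#' reads back. In `two_state` mode the ligand alternates between two poses
#' more than 5 Angstrom apart in ligand RMSD, giving the reference clustering
#' two clean binding modes; otherwise all frames share one pose (plus
#' sub-Angstrom thermal jitter).
#'
#' @param n_frames Number of frames (>= 1).
#' @param dir Output directory (created if missing).
#' @param two_state Alternate the ligand between two distant poses.
#' @param jitter Per-coordinate Gaussian noise in Angstrom (default 0.05).
#' @param seed Integer seed.
#' @return List with `topology` and `coords` file paths, plus `pose`
#'   (integer vector of the planted pose per frame).
#' @export
generate_toy_trajectory <- function(n_frames, dir = tempdir(), two_state = FALSE,
                                    jitter = 0.05, seed = 1) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # pseudo-protein: helix of 40 GLY residues x 3 atoms = 120 atoms
  nres <- 40L
  prot <- do.call(rbind, lapply(seq_len(nres), function(i) {
    ang <- i * 100 * pi / 180
    ca <- c(4 * cos(ang), 4 * sin(ang), 1.5 * i)
    rbind(ca, ca + c(1.2, 0, 0.3), ca + c(-0.4, 1.1, 0.6))
  }))
  # rigid 12-atom ligand template near the helix axis
  lig0 <- cbind(rep(c(0, 1.4, 2.8, 4.2), 3),
                rep(c(0, 1.2, 2.4), each = 4),
                rep(c(0, 0.8, 1.6), 4))
  pose_shift <- c(8, 0, 0)                     # second pose: > 5 A away
  center <- c(0, 0, 30)
  pose <- if (two_state) rep(c(0L, 1L), length.out = n_frames) else rep(0L, n_frames)
  natom <- nrow(prot) + nrow(lig0)
  xyz <- matrix(0, n_frames, 3L * natom)
  for (t in seq_len(n_frames)) {
    lig <- sweep(lig0, 2L, center + pose[t] * pose_shift, "+")
    coords <- rbind(prot, lig)
    coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter), nrow(coords))
    xyz[t, ] <- as.vector(t(coords))
  }
  atoms <- data.frame(
    name = c(rep(c("CA", "C", "N"), nres), sprintf("C%d", seq_len(nrow(lig0)))),
    resid = c(rep("GLY", 3L * nres), rep("LIG", nrow(lig0))),
    resno = c(rep(seq_len(nres), each = 3L), rep(nres + 1L, nrow(lig0)))
  )
  top <- file.path(dir, "toy_topology.pdb")
  crd <- file.path(dir, "toy_coords.pdb")
  write_multimodel_pdb(atoms, xyz[1L, , drop = FALSE], top)
  write_multimodel_pdb(atoms, xyz, crd)
  list(topology = top, coords = crd, pose = pose)
}

# Plain-text multi-model PDB writer (fixed-width ATOM records).
write_multimodel_pdb <- function(atoms, xyz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(atoms)
  for (t in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    for (i in seq_len(n)) {
      writeLines(sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         i, substr(atoms$name[i], 1, 4), substr(atoms$resid[i], 1, 3),
                         atoms$resno[i],
                         xyz[t, 3 * i - 2], xyz[t, 3 * i - 1], xyz[t, 3 * i],
                         1.0, 0.0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
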