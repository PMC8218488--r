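#' Configuration for an end-to-end moiety-ranking run
#'
#' Two input modes are supported: trajectory mode (topology + coordinates +
#' selections + force-field parameters, the full pipeline) and contact mode
#' (a precomputed `contact_series` + atom-to-subtype map, e.g. from
#' [generate_contact_system()], which skips trajectory reading and subtyping).
#'
#' @param topology,coords,ligand_selection,protein_selection Trajectory-mode
#'   inputs (see [load_trajectory()]).
#' @param params CHARMM parameter file path (or a parsed parameter tibble)
#'   for subtyping; trajectory mode only.
#' @param contacts Contact-mode input: a `contact_series` or a path readable
#'   by [read_contact_series()].
#' @param atom_to_subtype Contact-mode input: integer vector mapping ligand
#'   rows to subtype ids.
#' @param contact_cutoff Contact distance, Angstrom.
#' @param delta Dynamism lag in frames.
#' @param filters_grid,latent_grid Autoencoder ensemble grids.
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @param reference `"internal_rmsd"` (QT clustering of the trajectory, the
#'   default), `"external_file"` (CSV of frame,label) or `"all_atom_cvae"`
#'   (whole-molecule autoencoder + HDBSCAN).
#' @param reference_file Path or `cluster_assignment` for
#'   `reference = "external_file"`.
#' @param rmsd_cutoff QT-RMSD cutoff, Angstrom.
#' @param subtype_tolerance Relative tolerance for subtype grouping.
#' @param min_persist_ns Stability threshold for the reference mode, ns.
#' @param frame_interval_ps Snapshot spacing, ps.
#' @param max_epochs Autoencoder epoch cap (lower it for quick looks).
#' @param seed Base seed; all stage seeds derive from it.
#' @param output_dir If non-NULL, artifacts (metrics and ranking CSV, JSON
#'   report) are written here.
#' @return Object of class `run_config`.
#' @export
run_config <- function(topology = NULL, coords = NULL,
                       ligand_selection = NULL, protein_selection = NULL,
                       params = NULL, contacts = NULL, atom_to_subtype = NULL,
                       contact_cutoff = 4.5, delta = 500,
                       filters_grid = c(32, 64), latent_grid = c(3, 5, 10),
                       min_cluster_size = 50,
                       reference = c("internal_rmsd", "external_file", "all_atom_cvae"),
                       reference_file = NULL, rmsd_cutoff = 2.0,
                       subtype_tolerance = 0.10, min_persist_ns = 50,
                       frame_interval_ps = 20, max_epochs = 600,
                       seed = 1, output_dir = NULL) {
  reference <- match.arg(reference)
  traj_mode <- !is.null(topology)
  if (!traj_mode && is.null(contacts)) {
    stop("either trajectory inputs (topology, ...) or a contact series must be given",
         call. = FALSE)
  }
  if (traj_mode && (is.null(ligand_selection) || is.null(protein_selection))) {
    stop("trajectory mode needs ligand and protein selections", call. = FALSE)
  }
  if (!traj_mode && is.null(atom_to_subtype)) {
    stop("contact mode needs an atom_to_subtype map", call. = FALSE)
  }
  if (reference == "external_file" && is.null(reference_file)) {
    stop("reference = 'external_file' needs reference_file", call. = FALSE)
  }
  if (reference == "internal_rmsd" && !traj_mode) {
    stop("reference = 'internal_rmsd' needs trajectory inputs; use an external ",
         "reference or the all-atom autoencoder in contact mode", call. = FALSE)
  }
  stopifnot(length(filters_grid) >= 1, length(latent_grid) >= 1)
  structure(as.list(environment()), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full moiety-ranking pipeline
#'
#' Contacts -> subtypes -> dynamism -> per-subtype autoencoder ensemble ->
#' HDBSCAN -> cluster-size comparison against the whole-molecule reference ->
#' subtype ranking. Deterministic for a given config and seed; each stage
#' failure is reported with the stage name.
#'
#' @param config A [run_config()].
#' @return Object of class `moiety_report`: list with `ranking`
#'   (a `subtype_ranking`), `metrics` (per-subtype tibble), `stable`,
#'   `reference_sizes`, `subtype_sizes` (nested per-subtype/per-model list),
#'   `seeds`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traj <- NULL

  if (!is.null(config$topology)) {
    traj <- with_stage("load_trajectory",
      load_trajectory(config$topology, config$coords %||% config$topology,
                      config$ligand_selection, config$protein_selection,
                      config$frame_interval_ps))
    contacts <- with_stage("contacts",
      compute_contact_series(traj, config$contact_cutoff))
    a2s <- with_stage("subtypes", {
      par <- if (is.character(config$params)) parse_nonbonded_params(config$params)
             else config$params
      if (is.null(par)) stop("force-field parameters are required in trajectory mode")
      map_ligand_atoms(traj, group_subtypes(par, config$subtype_tolerance))
    })
  } else {
    contacts <- with_stage("contacts", {
      x <- config$contacts
      if (is.character(x)) x <- read_contact_series(x)
      stopifnot(inherits(x, "contact_series"))
      x
    })
    a2s <- as.integer(config$atom_to_subtype)
    if (length(a2s) != dim(contacts$values)[2]) {
      stop("pipeline stage 'subtypes' failed: atom_to_subtype length (",
           length(a2s), ") != ligand rows (", dim(contacts$values)[2], ")",
           call. = FALSE)
    }
  }
  T_ <- dim(contacts$values)[1]

  reference <- with_stage("reference", switch(config$reference,
    internal_rmsd = qt_rmsd_cluster(traj, config$rmsd_cutoff),
    external_file = {
      ref <- config$reference_file
      if (is.character(ref)) ref <- read_assignment(ref)
      stopifnot(inherits(ref, "cluster_assignment"))
      if (length(ref$labels) != T_) {
        stop("external reference has ", length(ref$labels),
             " frames but contacts have ", T_)
      }
      ref
    },
    all_atom_cvae = {
      dyn_all <- flatten_whole_molecule(build_dynamism(contacts, config$delta))
      cfg <- cvae_config(filters = config$filters_grid[1],
                         latent_dim = config$latent_grid[1],
                         max_epochs = config$max_epochs,
                         seed = config$seed %% .Machine$integer.max)
      emb <- train_cvae(build_cvae(cfg, dim(dyn_all$values)[2:4]), dyn_all)
      cluster_latent(emb, config$min_cluster_size)
    }))

  ref_sizes <- size_series(reference, identity = "molecule")
  stable <- is_stable(ref_sizes, config$frame_interval_ps, config$min_persist_ns)

  subtype_ids <- sort(unique(a2s))
  seeds <- stats::setNames(
    (config$seed + 1000L * seq_along(subtype_ids)) %% .Machine$integer.max,
    as.character(subtype_ids))
  subtype_sizes <- with_stage("embed+cluster", {
    out <- lapply(seq_along(subtype_ids), function(k) {
      sid <- subtype_ids[k]
      dyn <- build_dynamism(aggregate_by_subtype(contacts, a2s, sid), config$delta)
      embs <- build_ensemble(dyn$values, config$filters_grid, config$latent_grid,
                             base_seed = seeds[[k]], max_epochs = config$max_epochs)
      lapply(embs, function(e) {
        size_series(cluster_latent(e, config$min_cluster_size), identity = "subtype")
      })
    })
    names(out) <- as.character(subtype_ids)
    out
  })

  metrics <- with_stage("metrics", compare_subtypes(subtype_sizes, ref_sizes))
  ranking <- with_stage("ranking", rank_subtypes(metrics, stable))

  report <- structure(list(ranking = ranking, metrics = metrics, stable = stable,
                           reference_sizes = ref_sizes, subtype_sizes = subtype_sizes,
                           seeds = seeds, config = config),
                      class = "moiety_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.moiety_report <- function(x, ...) {
  cat("<moiety_report> ", nrow(x$ranking), " subtypes, reference ",
      if (x$stable) "STABLE" else "NOT stable", "\n", sep = "")
  print(tidy(x$ranking)[, c("subtype_id", "rank", "n_cos_sim", "n_avg_diff")])
  invisible(x)
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "subtype_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(report$ranking), file.path(dir, "subtype_ranking.csv"),
                   row.names = FALSE)
  cfg <- report$config
  cfg_echo <- cfg[!vapply(cfg, function(e)
    is.null(e) || inherits(e, "contact_series") || inherits(e, "cluster_assignment") ||
      is.data.frame(e), TRUE)]
  jsonlite::write_json(
    list(stable = report$stable,
         ranking = tidy(report$ranking),
         seeds = as.list(report$seeds),
         config = cfg_echo),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
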