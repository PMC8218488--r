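#' Load an MD trajectory with ligand/protein atom selections
#'
#' Reads a topology (PDB or PSF) and coordinates (DCD or multi-model PDB) and
#' returns a trajectory object holding all frames plus the two atom selections
#' the contact analysis needs. Atom order follows file order; frame order is
#' simulation-time order.
#'
#' Selections are compact expressions over the topology's atom table, combined
#' left to right with `and`:
#' \itemize{
#'   \item `protein` — standard amino-acid residues
#'   \item `resname XYZ` / `segid X` / `chain X` — field matches (several
#'     values may follow the keyword)
#'   \item `index a:b` — 1-based atom index range
#'   \item `noh` — drop hydrogens
#' }
#' e.g. `"resname LIG and noh"`.
#'
#' @param topology_path PDB or PSF file.
#' @param coords_path DCD or (multi-model) PDB file; may equal `topology_path`.
#' @param ligand_selection,protein_selection Selection expressions (above);
#'   must be non-empty and disjoint.
#' @param frame_interval_ps Time between saved snapshots in picoseconds
#'   (default 20, the usual snapshot spacing for ~100 ns production runs).
#' @return Object of class `md_trajectory`: list with `xyz` (T x 3A matrix,
#'   bio3d layout), `atoms` (data frame with `name`, `type`, `resid`, `resno`,
#'   `chain`, `segid`), `ligand`, `protein` (atom index vectors) and
#'   `frame_interval_ps`.
#' @export
load_trajectory <- function(topology_path, coords_path = topology_path,
                            ligand_selection, protein_selection,
                            frame_interval_ps = 20) {
  if (!file.exists(topology_path)) stop("topology file not found: ", topology_path, call. = FALSE)
  if (!file.exists(coords_path)) stop("coordinate file not found: ", coords_path, call. = FALSE)
  atoms <- read_topology(topology_path)
  xyz <- read_coords(coords_path)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("atom-count mismatch: topology has ", nrow(atoms), " atoms but coordinates have ",
         ncol(xyz) / 3, call. = FALSE)
  }
  lig <- select_atoms(atoms, ligand_selection)
  pro <- select_atoms(atoms, protein_selection)
  if (length(lig) == 0L) stop("ligand selection matches no atoms: ", ligand_selection, call. = FALSE)
  if (length(pro) == 0L) stop("protein selection matches no atoms: ", protein_selection, call. = FALSE)
  if (length(intersect(lig, pro)) > 0L) {
    stop("ligand and protein selections overlap (", length(intersect(lig, pro)),
         " shared atoms)", call. = FALSE)
  }
  new_trajectory(xyz, atoms, lig, pro, frame_interval_ps)
}

new_trajectory <- function(xyz, atoms, ligand, protein, frame_interval_ps = 20) {
  stopifnot(nrow(xyz) >= 1L, length(ligand) >= 1L, length(protein) >= 1L)
  structure(list(xyz = xyz, atoms = atoms, ligand = as.integer(ligand),
                 protein = as.integer(protein),
                 frame_interval_ps = frame_interval_ps),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames, ", length(x$ligand),
      " ligand + ", length(x$protein), " protein atoms (",
      nrow(x$atoms), " total), ", x$frame_interval_ps, " ps/frame\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `md_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

read_topology <- function(path) {
  if (grepl("\\.psf$", path, ignore.case = TRUE)) {
    read_psf_atoms(path)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    data.frame(name = a$elety, type = a$elety, resid = a$resid,
               resno = a$resno, chain = ifelse(is.na(a$chain), "", a$chain),
               segid = ifelse(is.na(a$segid) | a$segid == "", "", a$segid),
               stringsAsFactors = FALSE)
  }
}

# Minimal X-PLOR/CHARMM PSF atom-section reader (segid resno resid name type ...).
# No installed R package parses PSF, so the small fixed-column section is read here.
read_psf_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("!NATOM", lines)
  if (length(hdr) == 0L) stop("not a PSF file (no !NATOM section): ", path, call. = FALSE)
  natom <- as.integer(strsplit(trimws(lines[hdr[1]]), "\\s+")[[1]][1])
  rows <- lines[(hdr[1] + 1L):(hdr[1] + natom)]
  f <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(f, length, 0L) < 6L)
  if (length(bad) > 0L) stop("malformed PSF atom row ", bad[1], call. = FALSE)
  data.frame(
    name  = vapply(f, `[[`, "", 5L),
    type  = vapply(f, `[[`, "", 6L),
    resid = vapply(f, `[[`, "", 4L),
    resno = as.integer(vapply(f, `[[`, "", 3L)),
    chain = "",
    segid = vapply(f, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

read_coords <- function(path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    unclass(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    unclass(xyz)
  }
}

AMINO3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","HSD","HSE",
            "HSP","ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

select_atoms <- function(atoms, expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  keep <- rep(TRUE, nrow(atoms))
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks <- toks[toks != ""]
  i <- 1L
  take_values <- function(j) {
    vals <- character()
    while (j <= length(toks) && !toks[j] %in% c("and") &&
           !toks[j] %in% c("protein", "resname", "segid", "chain", "index", "noh", "all")) {
      vals <- c(vals, toks[j]); j <- j + 1L
    }
    list(vals = vals, nxt = j)
  }
  while (i <= length(toks)) {
    tok <- toks[i]
    if (tok == "and") { i <- i + 1L; next }
    if (tok == "all") { i <- i + 1L; next }
    if (tok == "protein") { keep <- keep & atoms$resid %in% AMINO3; i <- i + 1L; next }
    if (tok == "noh") { keep <- keep & !grepl("^[0-9]*H", atoms$name); i <- i + 1L; next }
    if (tok %in% c("resname", "segid", "chain")) {
      tv <- take_values(i + 1L)
      if (length(tv$vals) == 0L) stop("selection keyword '", tok, "' needs a value", call. = FALSE)
      field <- switch(tok, resname = atoms$resid, segid = atoms$segid, chain = atoms$chain)
      keep <- keep & field %in% tv$vals
      i <- tv$nxt; next
    }
    if (tok == "index") {
      tv <- take_values(i + 1L)
      if (length(tv$vals) == 0L) stop("selection keyword 'index' needs a range", call. = FALSE)
      idx <- integer()
      for (v in tv$vals) {
        if (grepl(":", v)) {
          ab <- as.integer(strsplit(v, ":")[[1]])
          idx <- c(idx, seq(ab[1], ab[2]))
        } else idx <- c(idx, as.integer(v))
      }
      keep <- keep & seq_len(nrow(atoms)) %in% idx
      i <- tv$nxt; next
    }
    stop("unknown selection token: '", tok, "'", call. = FALSE)
  }
  which(keep)
}
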