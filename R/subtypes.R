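#' Parse nonbonded Lennard-Jones parameters from CHARMM-style text
#'
#' Reads the `NONBONDED` section of a CHARMM `.prm`/`.str` parameter file and
#' returns one row per atom type with its Lennard-Jones well depth and size
#' parameter. CHARMM tables list the well depth as a negative number
#' (`epsilon` column) followed by `Rmin/2`; the well depth is stored as its
#' magnitude and `Rmin/2` is used directly as the particle-size parameter.
#'
#' @param x Either a path to a parameter file or a character vector of lines.
#' @return A tibble with columns `type_name`, `epsilon` (kcal/mol, >= 0) and
#'   `size` (Angstrom, `Rmin/2`). Duplicated type rows resolve to the last
#'   occurrence, with a warning.
#' @examples
#' txt <- c("NONBONDED", "CG331  0.0  -0.0780  2.0500", "HGA3   0.0  -0.0240  1.3400")
#' parse_nonbonded_params(txt)
#' @export
parse_nonbonded_params <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- sub("[!*].*$", "", lines)            # strip comments
  lines <- trimws(lines)
  start <- grep("^NONBONDED", lines)
  if (length(start) == 0L) {
    stop("no NONBONDED section found in parameter text", call. = FALSE)
  }
  body <- lines[(start[1] + 1L):length(lines)]
  # section ends at the next all-caps section keyword (BONDS, ANGLES, ...) or END
  stop_at <- grep("^(BONDS|ANGLES|DIHEDRALS|IMPROPERS|CMAP|NBFIX|HBOND|END|RETURN)\\b",
                  body)
  if (length(stop_at) > 0L) body <- body[seq_len(stop_at[1] - 1L)]
  body <- body[nzchar(body)]
  # continuation lines of the NONBONDED header (cutnb, ctofnb ...) start with '-'
  # or are option lines; data rows are: type ignored epsilon Rmin/2 [1-4 terms]
  recs <- list()
  for (ln in body) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 4L) next
    if (grepl("^[-0-9.]", f[1])) next           # header continuation
    eps <- suppressWarnings(as.numeric(f[3]))
    rmin2 <- suppressWarnings(as.numeric(f[4]))
    ign <- suppressWarnings(as.numeric(f[2]))
    if (is.na(ign)) next                        # not a data row
    if (is.na(eps) || is.na(rmin2)) {
      stop("non-numeric epsilon/Rmin2 fields in row: ", ln, call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- list(type_name = f[1], epsilon = abs(eps), size = rmin2)
  }
  if (length(recs) == 0L) stop("NONBONDED section contains no parameter rows", call. = FALSE)
  out <- tibble::tibble(
    type_name = vapply(recs, `[[`, "", "type_name"),
    epsilon   = vapply(recs, `[[`, 0.0, "epsilon"),
    size      = vapply(recs, `[[`, 0.0, "size")
  )
  if (anyDuplicated(out$type_name)) {
    dups <- unique(out$type_name[duplicated(out$type_name)])
    warning("duplicate atom type rows (last occurrence wins): ",
            paste(dups, collapse = ", "), call. = FALSE)
    out <- out[!duplicated(out$type_name, fromLast = TRUE), ]
  }
  out
}

#' Group force-field atom types into atom subtypes
#'
#' Two atom types are compatible when both their size and well-depth parameters
#' agree within a relative tolerance (default 10%), measured against the larger
#' value of the pair. Subtypes are the connected components of the resulting
#' compatibility graph, so the relation extends transitively and every type
#' belongs to exactly one subtype. Subtype IDs are contiguous from 0, assigned
#' by ascending (minimum size, minimum epsilon, lexicographically smallest type
#' name) of each component, which makes the table independent of input row
#' order.
#'
#' @param params Tibble/data frame from [parse_nonbonded_params()].
#' @param tolerance Relative tolerance; 0 groups only exactly equal parameters.
#' @return An object of class `subtype_table`: list with `subtype_of` (named
#'   integer vector, type name -> subtype id) and `members` (list of character
#'   vectors indexed by `id + 1`).
#' @examples
#' p <- tibble::tibble(type_name = c("A", "B", "C"),
#'                     epsilon = c(0.1, 0.1, 0.1), size = c(1.00, 1.09, 1.18))
#' group_subtypes(p)  # one subtype: A~B and B~C chain together
#' @export
group_subtypes <- function(params, tolerance = 0.10) {
  stopifnot(tolerance >= 0, nrow(params) >= 1L)
  n <- nrow(params)
  sz <- params$size
  ep <- params$epsilon
  ok_sz <- abs(outer(sz, sz, "-")) <= tolerance * outer(sz, sz, pmax)
  ok_ep <- abs(outer(ep, ep, "-")) <= tolerance * outer(ep, ep, pmax)
  adj <- ok_sz & ok_ep
  comp <- integer(n)                            # 0 = unvisited
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  # deterministic id assignment
  key <- data.frame(
    comp = seq_len(ncomp),
    min_size = vapply(seq_len(ncomp), function(k) min(sz[comp == k]), 0.0),
    min_eps  = vapply(seq_len(ncomp), function(k) min(ep[comp == k]), 0.0),
    min_name = vapply(seq_len(ncomp), function(k) min(params$type_name[comp == k]), "")
  )
  ord <- order(key$min_size, key$min_eps, key$min_name)
  new_id <- integer(ncomp)
  new_id[ord] <- seq_len(ncomp) - 1L
  subtype_of <- new_id[comp]
  names(subtype_of) <- params$type_name
  members <- lapply(seq_len(ncomp) - 1L, function(id) {
    sort(params$type_name[subtype_of == id])
  })
  structure(list(subtype_of = subtype_of, members = members),
            class = "subtype_table")
}

#' @export
print.subtype_table <- function(x, ...) {
  cat("<subtype_table> ", length(x$members), " subtypes over ",
      length(x$subtype_of), " atom types\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.subtype_table <- function(x, ...) {
  tibble::tibble(type_name = names(x$subtype_of),
                 subtype_id = unname(x$subtype_of))
}

#' Map ligand atoms to subtype IDs
#'
#' Looks up the force-field atom type of every ligand atom of a trajectory in a
#' subtype table. Protein atoms are untouched.
#'
#' @param traj A `md_trajectory` from [load_trajectory()].
#' @param table A `subtype_table` from [group_subtypes()].
#' @return Named integer vector: ligand atom index (within the ligand
#'   selection, 1-based) -> subtype id; names are the atom type labels.
#' @export
map_ligand_atoms <- function(traj, table) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(table, "subtype_table"))
  types <- traj$atoms$type[traj$ligand]
  unknown <- setdiff(unique(types), names(table$subtype_of))
  if (length(unknown) > 0L) {
    stop("atom type(s) not present in subtype table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- unname(table$subtype_of[types])
  names(out) <- types
  out
}

#' Write a subtype table to CSV
#'
#' @param table A `subtype_table`.
#' @param path Output CSV path (`type_name, subtype_id` rows).
#' @export
write_subtype_table <- function(table, path) {
  utils::write.csv(tidy(table), path, row.names = FALSE)
  invisible(path)
}
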