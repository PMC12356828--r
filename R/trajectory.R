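## Trajectory container and plain-text I/O (multi-model PDB, XYZ, and an
## atom-metadata sidecar TSV). Internal length unit is Angstrom throughout.

#' Construct a trajectory
#'
#' @param coords numeric array `frames x atoms x 3`, Angstrom.
#' @param atoms data.frame with columns `serial`, `element`, `vdw_radius`,
#'   `role` (protein/ligand/solvent/other), `hbond_class` (donor-heavy /
#'   hydrogen / acceptor / none), `bonded_heavy` (serial of the attached
#'   heavy atom, for hydrogens).
#' @param frame_spacing informational time between frames (ns).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, frame_spacing = NA_real_) {
  if (length(dim(coords)) != 3L || dim(coords)[[3L]] != 3L)
    abort("coords must be a frames x atoms x 3 array")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  req <- c("serial", "element", "vdw_radius", "role", "hbond_class",
           "bonded_heavy")
  missing <- setdiff(req, names(atoms))
  if (length(missing))
    abort(sprintf("atom table is missing column '%s'", missing[[1L]]))
  if (nrow(atoms) != dim(coords)[[2L]])
    abort("atom count must be constant across frames and match metadata")
  if (any(atoms$vdw_radius <= 0)) abort("vdw_radius must be > 0")
  hyd <- atoms$hbond_class == "hydrogen"
  if (any(hyd & is.na(atoms$bonded_heavy)))
    abort("every hydrogen needs a bonded_heavy serial")
  structure(list(coords = coords, atoms = atoms,
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms (%d protein, %d ligand)\n",
              n_frames(x), nrow(x$atoms), sum(x$atoms$role == "protein"),
              sum(x$atoms$role == "ligand")))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[[1L]]

#' @keywords internal
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(traj$atoms$serial, c("x", "y", "z")))
}

#' Write a trajectory as multi-model PDB plus metadata TSV
#'
#' Frames become `MODEL`/`ENDMDL` blocks; protein atoms are written as
#' `ATOM` records (residue `PRO`), ligand atoms as `HETATM` with residue
#' name `LIG`. Atom roles, radii and hydrogen-bond classes go to a sidecar
#' TSV because PDB has no field for them.
#'
#' @param traj a [trajectory()].
#' @param pdb_path,meta_path output paths (`meta_path` default:
#'   `<pdb_path>.meta.tsv`).
#' @return `pdb_path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, pdb_path,
                                 meta_path = paste0(pdb_path, ".meta.tsv")) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$atoms
  resname <- ifelse(at$role == "ligand", "LIG", "PRO")
  rectype <- ifelse(at$role == "ligand", "HETATM", "ATOM  ")
  con <- file(pdb_path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "%-6s%5d %-4s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, at$serial, substr(at$element, 1L, 2L), resname,
      ifelse(at$role == "ligand", 900L, 1L),
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  write_table(at, meta_path)
  invisible(pdb_path)
}

#' Read a multi-model PDB trajectory plus metadata TSV
#'
#' @param pdb_path multi-model PDB with `MODEL`/`ENDMDL` records.
#' @param meta_path atom-metadata TSV as written by
#'   [write_trajectory_pdb()].
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(pdb_path,
                                meta_path = paste0(pdb_path, ".meta.tsv")) {
  lines <- readLines(pdb_path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (!any(is_atom)) abort(sprintf("no ATOM records in %s", pdb_path))
  al <- lines[is_atom]
  mid <- model_id[is_atom]
  if (mid[[1L]] == 0L) mid <- mid + 1L   # single-frame file without MODEL
  xyz <- cbind(as.numeric(substr(al, 31L, 38L)),
               as.numeric(substr(al, 39L, 46L)),
               as.numeric(substr(al, 47L, 54L)))
  frames <- unique(mid)
  n_at <- sum(mid == frames[[1L]])
  coords <- array(NA_real_, dim = c(length(frames), n_at, 3L))
  for (k in seq_along(frames)) {
    sel <- mid == frames[[k]]
    if (sum(sel) != n_at)
      abort(sprintf("frame %d has %d atoms, expected %d", k, sum(sel), n_at))
    coords[k, , ] <- xyz[sel, , drop = FALSE]
  }
  atoms <- load_table(meta_path,
                      required_cols = c("serial", "element", "vdw_radius",
                                        "role", "hbond_class", "bonded_heavy"),
                      numeric_cols = c("serial", "vdw_radius", "bonded_heavy"))
  atoms$serial <- as.integer(atoms$serial)
  atoms$bonded_heavy <- as.integer(atoms$bonded_heavy)
  trajectory(coords, atoms)
}

#' Write / read a trajectory in XYZ format
#'
#' Plain multi-frame XYZ (atom count, comment, `element x y z` lines); the
#' atom metadata travels in the same sidecar TSV as the PDB dialect.
#'
#' @inheritParams write_trajectory_pdb
#' @param xyz_path path to the XYZ file.
#' @return the data path, invisibly (writer) or a [trajectory()] (reader).
#' @export
write_trajectory_xyz <- function(traj, xyz_path,
                                 meta_path = paste0(xyz_path, ".meta.tsv")) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(xyz_path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", nrow(xyz)), sprintf("frame %d", f),
                 sprintf("%-2s %12.6f %12.6f %12.6f", traj$atoms$element,
                         xyz[, 1L], xyz[, 2L], xyz[, 3L])), con)
  }
  write_table(traj$atoms, meta_path)
  invisible(xyz_path)
}

#' @rdname write_trajectory_xyz
#' @export
read_trajectory_xyz <- function(xyz_path,
                                meta_path = paste0(xyz_path, ".meta.tsv")) {
  lines <- readLines(xyz_path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[[i]]))) {
    n <- as.integer(trimws(lines[[i]]))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1L]] <-
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L)))
    i <- i + 2L + n
  }
  coords <- array(NA_real_, dim = c(length(frames), nrow(frames[[1L]]), 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  atoms <- load_table(meta_path,
                      required_cols = c("serial", "element", "vdw_radius",
                                        "role", "hbond_class", "bonded_heavy"),
                      numeric_cols = c("serial", "vdw_radius", "bonded_heavy"))
  atoms$serial <- as.integer(atoms$serial)
  atoms$bonded_heavy <- as.integer(atoms$bonded_heavy)
  trajectory(coords, atoms)
}
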