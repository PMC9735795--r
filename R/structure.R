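#' Trajectory container
#'
#' Ordered coordinate snapshots plus optional per-frame pulling channels
#' from a (steered) MD run.
#'
#' @param frames List of numeric coordinate matrices (rows = atoms,
#'   columns x/y/z, Angstrom), all with the same atoms in the same order
#'   and atom ids as row names.
#' @param pulling_force Optional per-frame pulling force,
#'   kcal mol^-1 A^-1.
#' @param reaction_coordinate Optional per-frame reaction coordinate,
#'   Angstrom.
#' @param timestep Optional time between frames (free units, metadata
#'   only).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, pulling_force = NULL,
                       reaction_coordinate = NULL, timestep = NULL) {
  if (length(frames) == 0) zf_error("zf_invalid_input", "no frames")
  n_atoms <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) {
    is.matrix(f) && nrow(f) == n_atoms && ncol(f) == 3 &&
      identical(rownames(f), rownames(frames[[1]]))
  }, logical(1))
  if (!all(ok)) {
    zf_error("zf_invalid_input",
             "all frames must share the same atoms in the same order")
  }
  for (ch in list(pulling_force, reaction_coordinate)) {
    if (!is.null(ch) && length(ch) != length(frames)) {
      zf_error("zf_invalid_input",
               "per-frame channels must match the number of frames")
    }
  }
  structure(
    list(frames = frames, pulling_force = pulling_force,
         reaction_coordinate = reaction_coordinate, timestep = timestep),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms%s\n",
              length(x$frames), nrow(x$frames[[1]]),
              if (!is.null(x$pulling_force)) " (+force/RC channels)" else ""))
  invisible(x)
}

#' Write / read a multi-frame XYZ trajectory
#'
#' Plain XYZ dialect: per frame an atom-count line, a comment line, then
#' one `id x y z` line per atom. Atom ids are free-form labels (stored as
#' row names); coordinates are in Angstrom.
#'
#' @param traj A [trajectory].
#' @param path Output file path.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a
#'   [trajectory] (without pulling channels; see
#'   [read_pulling_channels()]).
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(c(as.character(nrow(fr)), sprintf("frame %d", i)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", rownames(fr),
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) zf_error("zf_invalid_input", "malformed XYZ atom-count line")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    rownames(m) <- vapply(parts, `[[`, "", 1L)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  trajectory(frames)
}

#' Read a per-frame force / reaction-coordinate channel file
#'
#' CSV with header `frame,force,rc` matching the trajectory frame count.
#'
#' @param path CSV path.
#' @return Data frame with columns `frame`, `force`, `rc`.
#' @export
read_pulling_channels <- function(path) {
  d <- read.csv(path)
  if (!all(c("frame", "force", "rc") %in% names(d))) {
    zf_error("zf_invalid_input", "channel file needs columns frame,force,rc")
  }
  d
}

#' Coordinate matrix from a PDB file
#'
#' Reads ATOM/HETATM records via bio3d and returns the coordinate matrix
#' used by the geometry routines, with atom ids `"<elety>:<resno>"` (or
#' the atom serial number when `id = "eleno"`).
#'
#' @param path PDB file path.
#' @param id Either `"elety_resno"` (default) or `"eleno"`.
#' @return Numeric matrix (atoms x 3) with ids as row names.
#' @export
read_structure_pdb <- function(path, id = c("elety_resno", "eleno")) {
  id <- match.arg(id)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- if (id == "eleno") as.character(a$eleno)
                 else paste0(trimws(a$elety), ":", a$resno)
  m
}

#' Geometric hydrogen-bond detection
#'
#' Emits every donor/acceptor pair satisfying both criteria: donor-to-
#' acceptor heavy-atom distance below `d_max`, and deviation of the
#' D-H...A axis from linearity below `angle_max` (i.e. the angle at the
#' hydrogen between the H->D and H->A directions is within `angle_max`
#' degrees of 180).
#'
#' @param structure Numeric coordinate matrix (atoms x 3) with atom ids as
#'   row names (see [read_structure_pdb()]).
#' @param donors Data frame with columns `donor` and `hydrogen` (atom
#'   ids): each donor heavy atom with one of its attached hydrogens.
#' @param acceptors Character vector of acceptor atom ids.
#' @param d_max Distance cut-off, Angstrom (default 3.0).
#' @param angle_max Linearity-deviation cut-off, degrees (default 20).
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance` (D-A, Angstrom), `angle` (deviation from linearity,
#'   degrees); only qualifying bonds are returned.
#' @export
detect_hbonds <- function(structure, donors, acceptors,
                          d_max = 3.0, angle_max = 20.0) {
  ids <- rownames(structure)
  donors <- as.data.frame(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors))) {
    zf_error("zf_invalid_input", "donors needs columns donor and hydrogen")
  }
  missing <- setdiff(c(donors$donor, donors$hydrogen, acceptors), ids)
  if (length(missing) > 0) {
    zf_error("zf_selection_error",
             paste("atoms not present in structure:",
                   paste(missing, collapse = ", ")))
  }
  out <- data.frame(donor = character(0), hydrogen = character(0),
                    acceptor = character(0), distance = numeric(0),
                    angle = numeric(0))
  for (k in seq_len(nrow(donors))) {
    d_id <- donors$donor[k]; h_id <- donors$hydrogen[k]
    D <- structure[d_id, ]; H <- structure[h_id, ]
    for (a_id in acceptors) {
      if (a_id == d_id || a_id == h_id) next
      A <- structure[a_id, ]
      dist <- sqrt(sum((A - D)^2))
      if (dist >= d_max) next
      v1 <- D - H; v2 <- A - H
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi  # D-H-A angle
      dev <- 180 - theta
      if (dev >= angle_max) next
      out <- rbind(out, data.frame(donor = d_id, hydrogen = h_id,
                                   acceptor = a_id, distance = dist,
                                   angle = dev))
    }
  }
  out
}

# flatten an atoms x 3 matrix to the xyz vector layout bio3d expects
.as_xyz_vec <- function(m) as.numeric(t(m))

#' Root-mean-square deviation between two frames
#'
#' Standard RMSD over a selection of atoms, optionally after optimal
#' least-squares rigid-body superposition (Kabsch, via bio3d).
#'
#' @param frame,reference Coordinate matrices (atoms x 3) with matching
#'   atom ids.
#' @param selection Optional character vector of atom ids to include
#'   (default: all).
#' @param superpose Superpose `frame` onto `reference` first?
#' @return RMSD in Angstrom.
#' @export
rmsd_frames <- function(frame, reference, selection = NULL,
                        superpose = FALSE) {
  if (!is.null(selection)) {
    miss <- setdiff(selection, intersect(rownames(frame), rownames(reference)))
    if (length(miss) > 0) {
      zf_error("zf_selection_error",
               paste("selection atoms missing:", paste(miss, collapse = ", ")))
    }
    frame <- frame[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(frame) != nrow(reference)) {
    zf_error("zf_selection_error", "frames differ in atom count")
  }
  bio3d::rmsd(.as_xyz_vec(reference), .as_xyz_vec(frame), fit = superpose)
}

#' Root-mean-square fluctuation per atom over a trajectory
#'
#' RMSF of each selected atom about its mean position, optionally after
#' superposing every frame onto the first (recommended whenever the run
#' contains net rigid-body motion).
#'
#' @param traj A [trajectory].
#' @param selection Optional character vector of atom ids (default: all).
#' @param superpose Superpose frames onto the first frame before
#'   averaging?
#' @return Named numeric vector of per-atom RMSF values, Angstrom.
#' @export
rmsf_frames <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  frames <- traj$frames
  if (!is.null(selection)) {
    frames <- lapply(frames, function(f) f[selection, , drop = FALSE])
  }
  xyz <- t(vapply(frames, .as_xyz_vec, numeric(3 * nrow(frames[[1]]))))
  if (superpose && length(frames) > 1) {
    xyz <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz)
  }
  mu <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mu)^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  setNames(sqrt(rowSums(per_atom)), rownames(frames[[1]]))
}
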