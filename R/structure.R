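#' Water residue names recognised by default
#'
#' Residue names (case-insensitive) that mark a residue as a water molecule,
#' covering the PDB convention (HOH) and the common MD force-field water
#' models (TIP3P, TIP4P, SPC, GROMACS SOL, ...).
#'
#' @export
WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SPC", "SOL", "H2O")

#' Construct a molecular structure object
#'
#' The package's uniform data model: an atom table shared by one or more
#' coordinate frames. Produced by [read_pdb()], [read_mmcif()] and the
#' fixture generators; consumed by every analysis function.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resnum`, `chain`, `insert`, `altloc`, `occupancy`,
#'   `bfactor`, `is_water`, `is_hydrogen`. Missing bookkeeping columns are
#'   filled with defaults; `element` is inferred from `name` when absent.
#' @param coords numeric matrix (n_atoms x 3, one frame) or array
#'   (n_atoms x 3 x n_frames), coordinates in Angstrom.
#' @param frame_labels optional labels (e.g. MODEL numbers), one per frame.
#' @param water_names residue names treated as water (case-insensitive).
#' @return An object of class `wb_structure`.
#' @export
wb_structure <- function(atoms, coords, frame_labels = NULL,
                         water_names = WATER_RESNAMES) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  n <- nrow(atoms)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != n)
    stop(sprintf("coordinate frames have %d atoms but the atom table has %d",
                 dim(coords)[1], n))
  if (dim(coords)[3] < 1) stop("at least one coordinate frame is required")

  defaults <- list(serial = seq_len(n), name = NA_character_,
                   resname = "UNK", resnum = 1L, chain = "A",
                   insert = "", altloc = "", occupancy = 1, bfactor = 0)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  if (is.null(atoms$element) || all(is.na(atoms$element)) ||
      any(!nzchar(trimws(atoms$element)) | is.na(atoms$element))) {
    blank <- is.null(atoms$element) | is.na(atoms$element) |
      !nzchar(trimws(atoms$element %||% ""))
    inferred <- infer_element(atoms$name)
    atoms$element <- if (is.null(atoms$element)) inferred else
      ifelse(blank, inferred, toupper(trimws(atoms$element)))
  } else {
    atoms$element <- toupper(trimws(atoms$element))
  }
  atoms$is_water <- toupper(atoms$resname) %in% toupper(water_names)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  rownames(atoms) <- NULL

  if (!is.null(frame_labels) && length(frame_labels) != dim(coords)[3])
    stop("frame_labels length must equal the number of frames")
  structure(list(atoms = atoms, coords = coords,
                 frame_labels = frame_labels %||% seq_len(dim(coords)[3])),
            class = "wb_structure")
}

#' @export
print.wb_structure <- function(x, ...) {
  nw <- length(unique(residue_ids(x$atoms)[x$atoms$is_water]))
  cat(sprintf(
    "<wb_structure> %d atoms (%d hydrogens), %d water molecules, %d frame(s)\n",
    nrow(x$atoms), sum(x$atoms$is_hydrogen), nw, n_frames(x)))
  invisible(x)
}

#' Number of coordinate frames of a structure or trajectory
#' @param x a `wb_structure` or `wb_trajectory`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.wb_structure <- function(x) dim(x$coords)[3]

#' @export
n_frames.wb_trajectory <- function(x) x$n_frames

#' Extract one coordinate frame as an n x 3 matrix
#' @param x a `wb_structure` or `wb_trajectory`.
#' @param frame 1-based frame index.
#' @export
frame_coords <- function(x, frame = 1L) UseMethod("frame_coords")

#' @export
frame_coords.wb_structure <- function(x, frame = 1L) {
  if (frame < 1 || frame > n_frames(x))
    stop(sprintf("frame %d out of range (structure has %d frame(s))",
                 frame, n_frames(x)))
  m <- x$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
frame_coords.wb_trajectory <- function(x, frame = 1L) {
  if (frame < 1 || frame > x$n_frames)
    stop(sprintf("frame %d out of range (trajectory has %d frame(s))",
                 frame, x$n_frames))
  m <- x$coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Select atom indices by role
#'
#' Standard atom selections used throughout the package. Indices are
#' returned in ascending order.
#'
#' @param structure a `wb_structure`.
#' @param what one of `"protein-polar-heavy"` (N/O/S heavy atoms of
#'   non-water residues), `"water-oxygen"`, `"water-all"`, `"hydrogens"`,
#'   or a predicate function taking the atom table and returning a logical
#'   vector.
#' @return integer vector of 0 or more atom indices.
#' @export
select_atoms <- function(structure, what) {
  a <- structure$atoms
  keep <- if (is.function(what)) {
    what(a)
  } else {
    switch(what,
      "protein-polar-heavy" = !a$is_water & !a$is_hydrogen &
        a$element %in% c("N", "O", "S"),
      "water-oxygen" = a$is_water & a$element == "O",
      "water-all"    = a$is_water,
      "hydrogens"    = a$is_hydrogen,
      stop(sprintf("unknown selector '%s'", what))
    )
  }
  sort(which(keep))
}

#' Construct a trajectory object
#'
#' A topology (reference `wb_structure`, its first frame is the reference
#' coordinates) plus a stack of coordinate frames.
#'
#' @param topology a `wb_structure`.
#' @param coords n_atoms x 3 x n_frames array in Angstrom.
#' @param timestep optional time between stored frames, in ps.
#' @return An object of class `wb_trajectory`.
#' @export
wb_trajectory <- function(topology, coords, timestep = NULL) {
  stopifnot(inherits(topology, "wb_structure"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (dim(coords)[1] != nrow(topology$atoms))
    stop(sprintf("trajectory frames have %d atoms but topology has %d",
                 dim(coords)[1], nrow(topology$atoms)))
  if (dim(coords)[3] < 1) stop("a trajectory needs at least one frame")
  structure(list(topology = topology, coords = coords,
                 n_frames = dim(coords)[3], timestep = timestep),
            class = "wb_trajectory")
}

#' @export
print.wb_trajectory <- function(x, ...) {
  cat(sprintf("<wb_trajectory> %d atoms, %d frames%s\n",
              nrow(x$topology$atoms), x$n_frames,
              if (!is.null(x$timestep))
                sprintf(", %.4g ps/frame", x$timestep) else ""))
  invisible(x)
}

# Uniform accessors so analysis code can take either container.
as_topology <- function(x) {
  if (inherits(x, "wb_trajectory")) x$topology else x
}
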