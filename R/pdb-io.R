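#' Read a PDB file or text into the package data model
#'
#' Parses fixed-column PDB via bio3d, then normalises into the shared
#' atom-table + coordinate-frame model. Multi-MODEL files become one frame
#' per model, all sharing the atom table of the first model. Alternate
#' locations are reduced to a single conformer: the highest-occupancy
#' altloc wins, ties broken by altloc letter order.
#'
#' @param x path to a PDB file, or a character scalar/vector of PDB text.
#' @param water_names residue names flagged as water (case-insensitive).
#' @return A [wb_structure()].
#' @export
read_pdb <- function(x, water_names = WATER_RESNAMES) {
  lines <- pdb_text_lines(x)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom))
    stop("not a parseable PDB: no ATOM or HETATM records found")
  check_model_counts(lines, is_atom)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- suppressWarnings(
    bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE))

  atoms <- data.frame(
    serial = pdb$atom$eleno,
    name = pdb$atom$elety,
    element = pdb$atom$elesy %||% NA_character_,
    resname = pdb$atom$resid,
    resnum = pdb$atom$resno,
    chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
    insert = ifelse(is.na(pdb$atom$insert), "", pdb$atom$insert),
    altloc = ifelse(is.na(pdb$atom$alt), "", pdb$atom$alt),
    occupancy = ifelse(is.na(pdb$atom$o), 1, pdb$atom$o),
    bfactor = ifelse(is.na(pdb$atom$b), 0, pdb$atom$b),
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, nfr))
  for (f in seq_len(nfr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)

  keep <- resolve_altlocs(atoms)
  s <- wb_structure(atoms[keep, , drop = FALSE],
                    coords[keep, , , drop = FALSE],
                    frame_labels = seq_len(nfr),
                    water_names = water_names)
  s
}

pdb_text_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x)
  else unlist(strsplit(x, "\n", fixed = TRUE))
}

# Spec'd error contract: every MODEL block must carry the same atom count.
check_model_counts <- function(lines, is_atom) {
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible())
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  counts <- mapply(function(s, e) sum(is_atom[s:e]), starts,
                   ends[seq_along(starts)])
  labels <- sub("^MODEL\\s+", "", lines[starts])
  bad <- which(counts != counts[1])
  if (length(bad))
    stop(sprintf("MODEL %s has %d atoms; expected %d (as in MODEL %s)",
                 trimws(labels[bad[1]]), counts[bad[1]], counts[1],
                 trimws(labels[1])))
  invisible()
}

# Highest-occupancy altloc reduction; ties broken by altloc letter order.
resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(seq_len(nrow(atoms)))
  key <- paste(atoms$chain, atoms$resnum, atoms$insert, atoms$resname,
               atoms$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    ord <- order(-atoms$occupancy[idx], atoms$altloc[idx])
    idx[ord[1]]
  }), use.names = FALSE)
  sort(keep)
}

#' Write a structure as PDB text
#'
#' Fixed-column PDB v3.3 records via bio3d. Multi-frame output uses
#' MODEL/ENDMDL blocks. `bfactor_override` replaces the B-factor column,
#' the mechanism used to carry 0-1 bridge-frequency colour codes into
#' molecular viewers.
#'
#' @param structure a `wb_structure`.
#' @param file optional output path; when `NULL` the text is returned.
#' @param frame a single frame index, or `"all"` for every frame.
#' @param bfactor_override optional numeric vector, one value per atom.
#' @return The PDB text, invisibly when `file` is given.
#' @export
write_pdb <- function(structure, file = NULL, frame = "all",
                      bfactor_override = NULL) {
  a <- structure$atoms
  b <- a$bfactor
  if (!is.null(bfactor_override)) {
    if (length(bfactor_override) != nrow(a))
      stop(sprintf("bfactor_override has %d values but the structure has %d atoms",
                   length(bfactor_override), nrow(a)))
    b <- bfactor_override
  }
  frames <- if (identical(frame, "all")) seq_len(n_frames(structure)) else {
    if (!is.numeric(frame) || frame < 1 || frame > n_frames(structure))
      stop(sprintf("frame index %s out of range (1..%d)",
                   toString(frame), n_frames(structure)))
    as.integer(frame)
  }
  xyz <- t(vapply(frames, function(f) {
    as.vector(t(frame_coords(structure, f)))
  }, numeric(3 * nrow(a))))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  hetero <- structure$atoms$is_water | a$resname %in% c("DUM")
  bio3d::write.pdb(file = tf, xyz = xyz,
                   type = ifelse(hetero, "HETATM", "ATOM"),
                   resno = a$resnum, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, insert = a$insert,
                   o = a$occupancy, b = b, elesy = a$element,
                   verbose = FALSE)
  txt <- paste(readLines(tf), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
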