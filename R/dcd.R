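# Binary DCD trajectory I/O (CHARMM/NAMD layout): a "CORD" header with a
# 20-integer control block, a title record, an atom-count record, then per
# frame an optional unit-cell record (read and ignored) and three float32
# records (x, y, z). All records carry 4-byte Fortran length markers.
# Endianness is auto-detected from the first marker. The control block's
# delta field holds the timestep in AKMA units (1 AKMA = 0.04888821 ps).

AKMA_PS <- 0.04888821

#' Read a DCD trajectory
#'
#' @param path path to a binary DCD file.
#' @param topology a `wb_structure` whose atom count must match the file.
#' @return A [wb_trajectory()]; `timestep` in ps when the header carries one.
#' @export
read_dcd <- function(path, topology) {
  stopifnot(inherits(topology, "wb_structure"))
  con <- file(path, "rb")
  on.exit(close(con))

  m <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- if (identical(m, 84L)) "little" else {
    seek(con, 0)
    m2 <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (!identical(m2, 84L))
      stop("not a DCD file: header record length is not 84 in either byte order")
    "big"
  }
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stop(sprintf("not a DCD file: magic '%s'", magic))
  icntrl_raw <- readBin(con, "raw", 80)
  int_at <- function(i) readBin(icntrl_raw[(4 * (i - 1) + 1):(4 * i)],
                                "integer", 1, size = 4, endian = endian)
  flt_at <- function(i) readBin(icntrl_raw[(4 * (i - 1) + 1):(4 * i)],
                                "numeric", 1, size = 4, endian = endian)
  nframes_hdr <- int_at(1)
  nsavc <- int_at(3)
  delta <- flt_at(10)
  has_cell <- int_at(11) == 1L
  readBin(con, "integer", 1, size = 4, endian = endian)  # closing marker

  # title record
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", tlen)
  readBin(con, "integer", 1, size = 4, endian = endian)

  # atom count record
  readBin(con, "integer", 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  ntop <- nrow(topology$atoms)
  if (natom != ntop)
    stop(sprintf("DCD atom count (%d) does not match topology atom count (%d)",
                 natom, ntop))

  frames <- list()
  f <- 0L
  repeat {
    mk <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (!length(mk)) break
    f <- f + 1L
    if (has_cell) {
      if (mk != 48L) stop(sprintf("frame %d: malformed unit-cell record", f))
      readBin(con, "raw", 48)
      readBin(con, "integer", 1, size = 4, endian = endian)
      mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (!length(mk)) stop(sprintf("DCD truncated at frame %d", f))
    }
    xyz <- matrix(NA_real_, natom, 3)
    for (ax in 1:3) {
      if (ax > 1) mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (!length(mk) || mk != 4L * natom)
        stop(sprintf("DCD truncated at frame %d", f))
      v <- readBin(con, "numeric", natom, size = 4, endian = endian)
      if (length(v) != natom) stop(sprintf("DCD truncated at frame %d", f))
      xyz[, ax] <- v
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
    frames[[f]] <- xyz
  }
  if (f < 1) stop("DCD contains no frames")
  if (nframes_hdr > 0 && f != nframes_hdr)
    warning(sprintf("DCD header promises %d frames; %d read", nframes_hdr, f))
  coords <- array(unlist(frames), dim = c(natom, 3, f))
  ts <- if (delta > 0) delta * max(1L, nsavc) * AKMA_PS else NULL
  wb_trajectory(topology, coords, timestep = ts)
}

#' Write a DCD trajectory
#'
#' Used by the fixture generator and tests; real trajectories normally come
#' from a simulation engine.
#'
#' @param x a `wb_trajectory`, a multi-frame `wb_structure`, or an
#'   n_atoms x 3 x n_frames array.
#' @param path output path.
#' @param timestep time between frames in ps, stored in the header.
#' @param endian byte order to write (`"little"` or `"big"`).
#' @export
write_dcd <- function(x, path, timestep = NULL, endian = "little") {
  coords <- if (inherits(x, "wb_trajectory")) {
    if (is.null(timestep)) timestep <- x$timestep
    x$coords
  } else if (inherits(x, "wb_structure")) x$coords else x
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  natom <- dim(coords)[1]; nfr <- dim(coords)[3]

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = endian)
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = endian)

  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[20] <- 24L  # CHARMM-version flag: delta is a 32-bit float
  wi(84); writeBin(charToRaw("CORD"), con)
  for (i in 1:20) {
    if (i == 10 && !is.null(timestep)) wf(timestep / AKMA_PS) else wi(icntrl[i])
  }
  wi(84)
  title <- sprintf("%-80s", "REMARKS created by aquabridge")
  wi(4 + 80); wi(1); writeBin(charToRaw(title), con); wi(4 + 80)
  wi(4); wi(natom); wi(4)
  for (f in seq_len(nfr)) {
    for (ax in 1:3) {
      wi(4 * natom); wf(coords[, ax, f]); wi(4 * natom)
    }
  }
  invisible(path)
}
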