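#' Geometric criteria for water-bridge detection
#'
#' Bundles every tunable threshold of the detector. Angle ranges are
#' degrees at the hydrogen, measured between the H->donor-heavy-atom and
#' H->acceptor-heavy-atom vectors, so an ideal linear hydrogen bond scores
#' 180 degrees.
#'
#' @param distDA maximum donor to acceptor heavy-atom distance, Angstrom.
#' @param distWR maximum water-oxygen to protein-polar-atom distance
#'   defining the residue-water interaction shell, Angstrom.
#' @param anglePDWA allowed `c(lo, hi)` range for protein-donor -> H ->
#'   water-acceptor bonds, degrees.
#' @param anglePAWD allowed range for water-donor -> H -> protein-acceptor
#'   bonds, degrees.
#' @param angleWW allowed range for water -> H -> water bonds, degrees.
#' @param maxDepth maximum number of water molecules in a bridging chain.
#' @param angle_mode `"auto"` (use angles when the input has any hydrogen,
#'   else distance only), `"with-hydrogens"`, or `"angle-free"`.
#' @param max_donated_per_water,max_accepted_per_water per-water valence
#'   caps: a water molecule donates and accepts at most this many hydrogen
#'   bonds (2 each by default).
#' @param include_intra_residue report bridges whose two endpoints belong
#'   to the same residue (off by default).
#' @param water_names residue names treated as water.
#' @return A list of class `wb_criteria`.
#' @export
wb_criteria <- function(distDA = 3.5, distWR = 4.0,
                        anglePDWA = c(100, 180), anglePAWD = c(100, 180),
                        angleWW = c(140, 180), maxDepth = 2L,
                        angle_mode = c("auto", "with-hydrogens", "angle-free"),
                        max_donated_per_water = 2L,
                        max_accepted_per_water = 2L,
                        include_intra_residue = FALSE,
                        water_names = WATER_RESNAMES) {
  angle_mode <- match.arg(angle_mode)
  norm_range <- function(r, nm) {
    if (length(r) == 1) r <- c(r, 180)
    r <- sort(as.numeric(r))
    r[1] <- max(0, r[1]); r[2] <- min(180, r[2])
    if (r[1] > r[2]) stop(sprintf("%s: empty angle range", nm))
    r
  }
  if (distDA <= 0) stop("distDA must be positive")
  if (distWR <= 0) stop("distWR must be positive")
  if (maxDepth < 1) stop("maxDepth must be at least 1")
  structure(list(
    distDA = distDA, distWR = distWR,
    anglePDWA = norm_range(anglePDWA, "anglePDWA"),
    anglePAWD = norm_range(anglePAWD, "anglePAWD"),
    angleWW = norm_range(angleWW, "angleWW"),
    maxDepth = as.integer(maxDepth), angle_mode = angle_mode,
    max_donated_per_water = as.integer(max_donated_per_water),
    max_accepted_per_water = as.integer(max_accepted_per_water),
    include_intra_residue = isTRUE(include_intra_residue),
    water_names = water_names
  ), class = "wb_criteria")
}

#' @export
print.wb_criteria <- function(x, ...) {
  cat(format_criteria(x), sep = "\n")
  invisible(x)
}

format_criteria <- function(cr) {
  rng <- function(r) sprintf("[%g, %g]", r[1], r[2])
  c(sprintf("distDA=%g distWR=%g maxDepth=%d angle_mode=%s",
            cr$distDA, cr$distWR, cr$maxDepth, cr$angle_mode),
    sprintf("anglePDWA=%s anglePAWD=%s angleWW=%s",
            rng(cr$anglePDWA), rng(cr$anglePAWD), rng(cr$angleWW)),
    sprintf("max_donated_per_water=%d max_accepted_per_water=%d",
            cr$max_donated_per_water, cr$max_accepted_per_water))
}

# Resolve "auto" against a concrete structure.
resolve_angle_mode <- function(criteria, structure) {
  if (criteria$angle_mode != "auto") return(criteria$angle_mode)
  if (any(structure$atoms$is_hydrogen)) "with-hydrogens" else "angle-free"
}
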