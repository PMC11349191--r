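# Internal geometry and bookkeeping helpers.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Angle at a vertex, in degrees
#'
#' Returns the angle at `b` between the vectors `b -> a` and `b -> c`.
#' This is the convention used for the donor-H-acceptor angle: the vertex
#' is the hydrogen, the arms point to the two heavy atoms.
#' @keywords internal
#' @noRd
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ca <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# An arbitrary unit vector guaranteed not to be parallel to `v`.
any_perpendicular <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(ref - sum(ref * v) * v)
}

# Rotate unit vector `v` by `theta` degrees toward unit vector `axis_in_plane`
# (which must not be parallel to v); result stays in the span of the two.
rotate_in_plane <- function(v, axis_in_plane, theta) {
  perp <- axis_in_plane - sum(axis_in_plane * v) * v
  perp <- unit_vec(perp)
  cos(theta * pi / 180) * v + sin(theta * pi / 180) * perp
}

# Residue identity string "chain:resnum[insert]:resname" used in all outputs.
residue_ids <- function(atoms) {
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  sprintf("%s:%s%s:%s", atoms$chain, atoms$resnum, ins, atoms$resname)
}

# Canonical unordered residue-pair key.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

# Infer an element symbol from a PDB atom name when the element column is
# blank. Leading digits/primes are stripped; names beginning with H or D
# (including "1HB"-style) are hydrogens/deuteriums.
infer_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (nm == "") return("X")
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restore-on-exit seeded RNG scope so fixture generation never perturbs the
# caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}
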