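# Hydrogen-bond detection under the configurable geometric criteria.

# Cell-list neighbour search: all unordered pairs within `cutoff`.
# Returns a data.frame (i, j, distance) with i < j (indices into xyz rows).
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (is.null(n) || n < 2) return(empty)
  lo <- apply(xyz, 2, min)
  cell <- floor(sweep(xyz, 2, lo) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cellmap <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  for (ck in names(cellmap)) {
    ijk <- as.numeric(strsplit(ck, " ", fixed = TRUE)[[1]])
    members <- cellmap[[ck]]
    neigh <- unlist(lapply(seq_len(27), function(o) {
      cellmap[[paste(ijk[1] + offs[o, 1], ijk[2] + offs[o, 2],
                     ijk[3] + offs[o, 3])]]
    }), use.names = FALSE)
    for (i in members) {
      js <- neigh[neigh > i]
      if (!length(js)) next
      d2 <- colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2)
      keep <- d2 <= cutoff^2
      if (any(keep)) {
        k <- k + 1L
        out_i[[k]] <- rep.int(i, sum(keep))
        out_j[[k]] <- js[keep]
        out_d[[k]] <- sqrt(d2[keep])
      }
    }
  }
  if (!k) return(empty)
  res <- data.frame(i = unlist(out_i), j = unlist(out_j),
                    distance = unlist(out_d))
  res[order(res$i, res$j), , drop = FALSE]
}

hb_kind <- function(structure, donor, acceptor) {
  dw <- structure$atoms$is_water[donor]
  aw <- structure$atoms$is_water[acceptor]
  if (dw && aw) "water-water"
  else if (!dw && !aw) "protein-protein"
  else "protein-water"
}

applicable_range <- function(criteria, structure, donor, acceptor) {
  dw <- structure$atoms$is_water[donor]
  aw <- structure$atoms$is_water[acceptor]
  if (dw && aw) criteria$angleWW
  else if (dw) criteria$anglePAWD      # water donates to protein acceptor
  else criteria$anglePDWA              # protein donates (to water or protein)
}

#' Evaluate one candidate hydrogen bond
#'
#' Accepts iff the donor-acceptor heavy-atom distance is within `distDA`
#' and, in with-hydrogens mode, some hydrogen covalently attached to the
#' donor gives a donor-H-acceptor angle (measured at the hydrogen) inside
#' the applicable range: `anglePDWA` when a protein atom donates,
#' `anglePAWD` when a water donates to a protein acceptor, `angleWW`
#' between waters. In angle-free mode the distance test alone decides.
#' The best (largest-angle) hydrogen is reported. Donors with
#' rotamer-dependent missing hydrogens (Ser/Thr/Tyr hydroxyls, Lys NZ,
#' Cys SG) fall back to angle-free acceptance for that atom.
#'
#' @param structure a `wb_structure` with roles assignable.
#' @param donor,acceptor atom indices (heavy atoms, different residues).
#' @param frame frame index, or an n x 3 coordinate matrix.
#' @param criteria a [wb_criteria()].
#' @param roles optional precomputed [assign_roles()] vector.
#' @param angle_mode optional resolved mode (bypasses `"auto"`).
#' @return A one-row data.frame (donor, hydrogen, acceptor, distance,
#'   angle, kind) or `NULL` when rejected.
#' @export
detect_hbond <- function(structure, donor, acceptor, frame = 1L,
                         criteria = wb_criteria(), roles = NULL,
                         angle_mode = NULL) {
  xyz <- if (is.matrix(frame)) frame else frame_coords(structure, frame)
  a <- structure$atoms
  if (a$chain[donor] == a$chain[acceptor] &&
      a$resnum[donor] == a$resnum[acceptor] &&
      a$insert[donor] == a$insert[acceptor]) return(NULL)
  d <- vec_norm(xyz[donor, ] - xyz[acceptor, ])
  if (d > criteria$distDA) return(NULL)
  mode <- angle_mode %||% resolve_angle_mode(criteria, structure)
  kind <- hb_kind(structure, donor, acceptor)
  rec <- function(h, ang) data.frame(
    donor = donor, hydrogen = h, acceptor = acceptor, distance = d,
    angle = ang, kind = kind, stringsAsFactors = FALSE)

  if (mode == "angle-free") return(rec(NA_integer_, NA_real_))
  hs <- attached_hydrogens(structure, xyz, donor)
  if (!length(hs)) {
    key <- paste(toupper(trimws(a$resname[donor])),
                 toupper(trimws(a$name[donor])), sep = "|")
    if (key %in% ROTATABLE_DONOR) return(rec(NA_integer_, NA_real_))
    if (isTRUE(getOption("aquabridge.verbose", FALSE)))
      message(sprintf("donor atom %d has no attached hydrogen; rejected",
                      donor))
    return(NULL)
  }
  angs <- vapply(hs, function(h)
    angle_deg(xyz[donor, ], xyz[h, ], xyz[acceptor, ]), numeric(1))
  best <- which.max(angs)
  rng <- applicable_range(criteria, structure, donor, acceptor)
  if (angs[best] >= rng[1] && angs[best] <= rng[2])
    rec(hs[best], angs[best])
  else NULL
}

#' Build the hydrogen-bond graph of one frame
#'
#' Evaluates every candidate donor/acceptor pair within `distDA` over the
#' protein polar heavy atoms and water oxygens, using a spatial cell list
#' (no all-pairs scan), then applies the per-water valence cap: each water
#' keeps at most `max_donated_per_water` donated and
#' `max_accepted_per_water` accepted bonds, dropping the longest-distance
#' excess (ties broken by lower partner atom index). Protein-protein
#' hydrogen bonds are recorded but flagged; they never serve as bridge
#' edges.
#'
#' @param structure a `wb_structure`.
#' @param frame frame index.
#' @param criteria a [wb_criteria()].
#' @return An object of class `wb_hbond_graph`: list with `edges` (one row
#'   per directed donor->acceptor bond), `frame`, `criteria`, `roles`,
#'   `angle_mode` and the source `structure`.
#' @export
hbond_graph <- function(structure, frame = 1L, criteria = wb_criteria()) {
  roles <- assign_roles(structure)
  mode <- resolve_angle_mode(criteria, structure)
  xyz <- frame_coords(structure, frame)
  cand <- sort(union(select_atoms(structure, "protein-polar-heavy"),
                     select_atoms(structure, "water-oxygen")))
  cand <- cand[roles[cand] != "none"]
  edges <- list(); k <- 0L
  if (length(cand) >= 2) {
    pr <- neighbor_pairs(xyz[cand, , drop = FALSE], criteria$distDA)
    for (r in seq_len(nrow(pr))) {
      i <- cand[pr$i[r]]; j <- cand[pr$j[r]]
      if (roles[i] %in% c("donor", "both") &&
          roles[j] %in% c("acceptor", "both")) {
        hb <- detect_hbond(structure, i, j, xyz, criteria, roles, mode)
        if (!is.null(hb)) { k <- k + 1L; edges[[k]] <- hb }
      }
      if (roles[j] %in% c("donor", "both") &&
          roles[i] %in% c("acceptor", "both")) {
        hb <- detect_hbond(structure, j, i, xyz, criteria, roles, mode)
        if (!is.null(hb)) { k <- k + 1L; edges[[k]] <- hb }
      }
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), distance = numeric(0),
               angle = numeric(0), kind = character(0))
  edges <- prune_water_valence(edges, structure, criteria)
  rownames(edges) <- NULL
  structure(list(edges = edges, frame = frame, criteria = criteria,
                 roles = roles, angle_mode = mode, structure = structure),
            class = "wb_hbond_graph")
}

# Per-water valence cap. Ranks are computed on the unpruned list; a bond
# survives only if it sits within the cap at every water endpoint.
prune_water_valence <- function(edges, structure, criteria) {
  if (!nrow(edges)) return(edges)
  wat <- structure$atoms$is_water
  rank_within <- function(endpoint, partner) {
    r <- integer(nrow(edges))
    grp <- split(seq_len(nrow(edges)), edges[[endpoint]])
    for (idx in grp) {
      ord <- order(edges$distance[idx], edges[[partner]][idx])
      r[idx[ord]] <- seq_along(idx)
    }
    r
  }
  don_rank <- rank_within("donor", "acceptor")
  acc_rank <- rank_within("acceptor", "donor")
  keep <- rep(TRUE, nrow(edges))
  keep[wat[edges$donor] & don_rank > criteria$max_donated_per_water] <- FALSE
  keep[wat[edges$acceptor] & acc_rank > criteria$max_accepted_per_water] <- FALSE
  edges[keep, , drop = FALSE]
}

#' @export
print.wb_hbond_graph <- function(x, ...) {
  cat(sprintf("<wb_hbond_graph> frame %d: %d bonds (%s mode)\n",
              x$frame, nrow(x$edges), x$angle_mode))
  if (nrow(x$edges)) print(table(x$edges$kind))
  invisible(x)
}
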