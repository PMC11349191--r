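#' Place missing water hydrogens
#'
#' Waters that carry no hydrogen get two, at 0.96 Angstrom O-H bond length
#' and a 104.5 degree H-O-H angle. The first hydrogen points at the
#' nearest acceptor within `distDA` when one exists (so a plantable
#' hydrogen bond becomes near-linear); otherwise a deterministic arbitrary
#' orientation is used. The second hydrogen is opened 104.5 degrees from
#' the first, steered toward the second-nearest acceptor when available.
#' Protein donors are never modified: rotamer-dependent hydrogens are not
#' fabricated, the angle-free fallback handles those donors instead.
#' Idempotent on structures that already carry hydrogens.
#'
#' @param structure a `wb_structure`.
#' @param criteria a [wb_criteria()]; only `distDA` is used here.
#' @return A `wb_structure` with hydrogens appended after each bare water
#'   oxygen (all frames placed frame-wise).
#' @export
place_missing_hydrogens <- function(structure, criteria = wb_criteria()) {
  a <- structure$atoms
  wat_o <- select_atoms(structure, "water-oxygen")
  if (!length(wat_o)) return(structure)

  bare <- wat_o[vapply(wat_o, function(i) {
    length(attached_hydrogens(structure, frame_coords(structure, 1), i)) == 0
  }, logical(1))]
  if (!length(bare)) return(structure)

  roles <- assign_roles(structure)
  acc <- which(roles %in% c("acceptor", "both") & !a$is_hydrogen)
  nfr <- n_frames(structure)
  n_new <- 2L * length(bare)
  new_xyz <- array(NA_real_, dim = c(n_new, 3, nfr))

  for (f in seq_len(nfr)) {
    xyz <- frame_coords(structure, f)
    row <- 0L
    for (i in bare) {
      o <- xyz[i, ]
      others <- setdiff(acc, i)
      d <- if (length(others))
        sqrt(colSums((t(xyz[others, , drop = FALSE]) - o)^2)) else numeric(0)
      near <- others[order(d)][d[order(d)] <= criteria$distDA]
      d1 <- if (length(near) >= 1) unit_vec(xyz[near[1], ] - o) else c(1, 0, 0)
      steer <- if (length(near) >= 2) unit_vec(xyz[near[2], ] - o)
               else any_perpendicular(d1)
      if (abs(sum(steer * d1)) > 0.999) steer <- any_perpendicular(d1)
      d2 <- rotate_in_plane(d1, steer, 104.5)
      new_xyz[row + 1L, , f] <- o + 0.96 * d1
      new_xyz[row + 2L, , f] <- o + 0.96 * d2
      row <- row + 2L
    }
  }

  new_rows <- do.call(rbind, lapply(seq_along(bare), function(k) {
    i <- bare[k]
    data.frame(serial = NA_integer_, name = c("H1", "H2"), element = "H",
               resname = a$resname[i], resnum = a$resnum[i],
               chain = a$chain[i], insert = a$insert[i], altloc = "",
               occupancy = 1, bfactor = 0, is_water = TRUE,
               is_hydrogen = TRUE, stringsAsFactors = FALSE)
  }))

  # interleave: each bare water's hydrogens directly after its oxygen
  ord_atoms <- rbind(a[, names(new_rows)], new_rows)
  pos <- c(seq_len(nrow(a)), rep(bare, each = 2) + c(0.1, 0.2))
  ord <- order(pos)
  all_xyz <- array(NA_real_, dim = c(nrow(ord_atoms), 3, nfr))
  for (f in seq_len(nfr))
    all_xyz[, , f] <- rbind(frame_coords(structure, f), new_xyz[, , f])[ord, ]
  out_atoms <- ord_atoms[ord, , drop = FALSE]
  out_atoms$serial <- seq_len(nrow(out_atoms))
  wb_structure(out_atoms, all_xyz, frame_labels = structure$frame_labels,
               water_names = criteria$water_names)
}
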