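# Synthetic structures and trajectories with planted, exactly known water
# bridges, occupancy patterns and hydration sites. The geometry is ideal
# (O...O 2.8 Angstrom, linear donor-H...acceptor), not simulated, so every
# planted interaction is detectable by construction and every decoy is
# excluded by construction; both facts are asserted at generation time.

#' Specification of a synthetic fixture
#'
#' @param planted_depths water-chain depth of each planted bridge (one
#'   residue pair per entry).
#' @param occupancy_p per-frame Bernoulli probability that a planted
#'   bridge is "on" in a trajectory fixture.
#' @param n_frames number of trajectory frames.
#' @param n_decoy_waters waters placed far (>= distDA + 1) from every
#'   polar atom.
#' @param site_centers k x 3 matrix of planted hydration-site centers
#'   (pairwise >= 5 * site_sigma apart).
#' @param site_sigma isotropic Gaussian spread of site observations,
#'   Angstrom.
#' @param n_per_site observations drawn per site.
#' @param n_noise uniform noise observations.
#' @param distance_jitter either a scalar half-width (uniform jitter of
#'   the endpoint distance on "on" frames) or a vector of planted offsets
#'   recycled over on-frames.
#' @param timestep trajectory timestep in ps.
#' @param seed RNG seed (Mersenne-Twister); fixed seed means bit-identical
#'   output.
#' @return list of class `wb_fixture_spec`.
#' @export
fixture_spec <- function(planted_depths = c(1L, 2L), occupancy_p = 0.7,
                         n_frames = 10L, n_decoy_waters = 6L,
                         site_centers = rbind(c(0, 0, 0), c(6, 0, 0),
                                              c(0, 6, 0)),
                         site_sigma = 0.3, n_per_site = 50L, n_noise = 0L,
                         distance_jitter = 0, timestep = 1.0, seed = 42L) {
  stopifnot(all(planted_depths >= 1), occupancy_p >= 0, occupancy_p <= 1,
            n_frames >= 1, n_decoy_waters >= 0, site_sigma > 0)
  structure(list(planted_depths = as.integer(planted_depths),
                 occupancy_p = occupancy_p, n_frames = as.integer(n_frames),
                 n_decoy_waters = as.integer(n_decoy_waters),
                 site_centers = site_centers, site_sigma = site_sigma,
                 n_per_site = as.integer(n_per_site),
                 n_noise = as.integer(n_noise),
                 distance_jitter = distance_jitter, timestep = timestep,
                 seed = as.integer(seed)),
            class = "wb_fixture_spec")
}

OO_SPACING <- 2.8   # ideal hydrogen-bond O...O / N...O separation
ROW_SPACING <- 15   # separation between planted bridge rows
DECOY_Z <- 40       # decoy layer height

#' Build a structure with planted water bridges
#'
#' Each planted bridge is a pair of glycine-like pseudo-residues (a donor
#' N-H on one side, an acceptor carbonyl O on the other) joined by a
#' collinear chain of `depth` waters at 2.8 Angstrom spacing with linear
#' donor-H-acceptor geometry. Pairs sit on separate rows 15 Angstrom
#' apart; decoy waters sit on a distant layer. The returned truth table
#' lists every planted pair with its depth and water ids.
#'
#' @param spec a [fixture_spec()].
#' @param criteria criteria the fixture must satisfy (used for the
#'   generation-time soundness assertions and decoy placement).
#' @return list: `structure` (a `wb_structure` with hydrogens),
#'   `truth` (data.frame: pair, res_a, res_b, depth, waters).
#' @export
make_bridge_fixture <- function(spec = fixture_spec(),
                                criteria = wb_criteria()) {
  depths <- spec$planted_depths
  rows <- list(); k <- 0L
  wat_num <- 100L
  add <- function(name, element, resname, resnum, chain, x, y, z) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(serial = k, name = name, element = element,
                             resname = resname, resnum = resnum,
                             chain = chain, insert = "", altloc = "",
                             occupancy = 1, bfactor = 0, x = x, y = y,
                             z = z, stringsAsFactors = FALSE)
  }
  truth <- list()
  h2dir <- c(cos(104.5 * pi / 180), 0, sin(104.5 * pi / 180))
  for (p in seq_along(depths)) {
    d <- depths[p]
    y <- (p - 1) * ROW_SPACING
    ra <- 2L * p - 1L; rb <- 2L * p
    # donor-side residue: backbone N-H aimed along +x at the water chain
    add("N", "N", "GLY", ra, "A", 0, y, 0)
    add("H", "H", "GLY", ra, "A", 1.00, y, 0)
    add("CA", "C", "GLY", ra, "A", -1.2, y, 1.0)
    add("C", "C", "GLY", ra, "A", -2.6, y, 0.6)
    add("O", "O", "GLY", ra, "A", -3.2, y, 1.6)
    wids <- character(d)
    for (i in seq_len(d)) {
      wn <- wat_num
      wat_num <- wat_num + 1L
      ox <- OO_SPACING * i
      add("O", "O", "HOH", wn, "W", ox, y, 0)
      add("H1", "H", "HOH", wn, "W", ox + 0.96, y, 0)
      add("H2", "H", "HOH", wn, "W", ox + 0.96 * h2dir[1], y,
          0.96 * h2dir[3])
      wids[i] <- sprintf("W:%d:HOH", wn)
    }
    # acceptor-side residue: carbonyl O facing the last water
    bx <- OO_SPACING * (d + 1)
    add("O", "O", "GLY", rb, "A", bx, y, 0)
    add("C", "C", "GLY", rb, "A", bx + 1.2, y, 0.3)
    add("CA", "C", "GLY", rb, "A", bx + 2.4, y, 1.2)
    add("N", "N", "GLY", rb, "A", bx + 3.8, y, 1.2)
    add("H", "H", "GLY", rb, "A", bx + 4.7, y, 1.2)
    truth[[p]] <- data.frame(
      pair = p, res_a = sprintf("A:%d:GLY", ra),
      res_b = sprintf("A:%d:GLY", rb), depth = d,
      waters = paste(wids, collapse = ","), stringsAsFactors = FALSE)
  }
  for (j in seq_len(spec$n_decoy_waters)) {
    wn <- wat_num; wat_num <- wat_num + 1L
    x <- 6 * ((j - 1) %% 5); y <- 6 * ((j - 1) %/% 5)
    add("O", "O", "HOH", wn, "W", x, y, DECOY_Z)
    add("H1", "H", "HOH", wn, "W", x + 0.96, y, DECOY_Z)
    add("H2", "H", "HOH", wn, "W", x + 0.96 * h2dir[1], y,
        DECOY_Z + 0.96 * h2dir[3])
  }
  tab <- do.call(rbind, rows)
  s <- wb_structure(tab[, 1:10], as.matrix(tab[, c("x", "y", "z")]),
                    water_names = criteria$water_names)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(pair = integer(0), res_a = character(0),
               res_b = character(0), depth = integer(0),
               waters = character(0))
  assert_fixture_sound(s, truth, criteria)
  list(structure = s, truth = truth)
}

# Generation-time soundness: every planted consecutive contact passes
# detect_hbond; every decoy oxygen is at least distDA + 1 from all polar
# atoms of the bridge rows.
assert_fixture_sound <- function(s, truth, criteria) {
  a <- s$atoms
  rid <- residue_ids(a)
  roles <- assign_roles(s)
  xyz <- frame_coords(s, 1)
  find_atom <- function(res, nm)
    which(rid == res & trimws(a$name) == nm)[1]
  for (r in seq_len(nrow(truth))) {
    wids <- strsplit(truth$waters[r], ",")[[1]]
    chain_atoms <- c(find_atom(truth$res_a[r], "N"),
                     vapply(wids, find_atom, integer(1), nm = "O"),
                     find_atom(truth$res_b[r], "O"))
    for (i in seq_len(length(chain_atoms) - 1)) {
      hb <- detect_hbond(s, chain_atoms[i], chain_atoms[i + 1], xyz,
                         criteria, roles, "with-hydrogens")
      if (is.null(hb))
        stop(sprintf("fixture generation failed: planted contact %d-%d of pair %d does not pass detection",
                     chain_atoms[i], chain_atoms[i + 1], r))
    }
  }
  decoy_o <- which(a$is_water & a$element == "O" &
                   xyz[, 3] >= DECOY_Z - 1e-9)
  polar <- setdiff(sort(c(select_atoms(s, "protein-polar-heavy"),
                          select_atoms(s, "water-oxygen"))), decoy_o)
  if (length(decoy_o) && length(polar)) {
    for (dd in decoy_o) {
      dmin <- min(sqrt(colSums((t(xyz[polar, , drop = FALSE]) -
                                  xyz[dd, ])^2)))
      if (dmin < criteria$distDA + 1)
        stop("fixture generation failed: a decoy water sits inside the detection shell")
    }
  }
  invisible(TRUE)
}

#' Build a trajectory with planted per-frame bridge occupancy
#'
#' Starting from [make_bridge_fixture()], each planted bridge is "on" in
#' a frame with probability `occupancy_p` (seeded). Off-frames displace
#' that bridge's waters by 3 x distDA; on-frames optionally shift the
#' acceptor residue along the chain axis by a planted jitter so endpoint
#' distances vary by a known amount. The truth records the realized
#' on/off state and endpoint distance of every bridge in every frame.
#'
#' @inheritParams make_bridge_fixture
#' @return list: `trajectory` (a `wb_trajectory`), `structure` (the same
#'   frames as a multi-frame `wb_structure`), `truth` (data.frame: frame,
#'   pair, on, distance_AB), `base` (the frame-0 fixture).
#' @export
make_trajectory_fixture <- function(spec = fixture_spec(),
                                    criteria = wb_criteria()) {
  base <- make_bridge_fixture(spec, criteria)
  s <- base$structure
  a <- s$atoms
  rid <- residue_ids(a)
  xyz0 <- frame_coords(s, 1)
  np <- nrow(base$truth)
  nf <- spec$n_frames

  with_seed(spec$seed, {
    on_mat <- matrix(stats::runif(nf * np) < spec$occupancy_p, nf, np)
    jit <- spec$distance_jitter
    jitter_for <- function(n_on) {
      if (length(jit) > 1) rep_len(jit, n_on)
      else if (jit > 0) stats::runif(n_on, -jit, jit)
      else numeric(n_on)
    }
    coords <- array(NA_real_, dim = c(nrow(a), 3, nf))
    truth <- list(); tr <- 0L
    for (p in seq_len(np)) {
      d <- base$truth$depth[p]
      base_dist <- OO_SPACING * (d + 1)
      wids <- strsplit(base$truth$waters[p], ",")[[1]]
      wat_atoms <- which(rid %in% wids)
      b_atoms <- which(rid == base$truth$res_b[p])
      deltas <- numeric(nf)
      deltas[on_mat[, p]] <- jitter_for(sum(on_mat[, p]))
      for (f in seq_len(nf)) {
        if (p == 1) coords[, , f] <- xyz0
        if (!on_mat[f, p]) {
          coords[wat_atoms, 3, f] <- coords[wat_atoms, 3, f] +
            3 * criteria$distDA
        } else if (deltas[f] != 0) {
          coords[b_atoms, 1, f] <- coords[b_atoms, 1, f] + deltas[f]
        }
        tr <- tr + 1L
        truth[[tr]] <- data.frame(
          frame = f, pair = p, on = on_mat[f, p],
          distance_AB = if (on_mat[f, p]) base_dist + deltas[f] else NA_real_)
      }
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$frame, truth$pair), ]
    rownames(truth) <- NULL
    traj <- wb_trajectory(s, coords, timestep = spec$timestep)
    ms <- wb_structure(a, coords, water_names = criteria$water_names)
    list(trajectory = traj, structure = ms, truth = truth, base = base)
  })
}

#' Build a pool of water-oxygen observations with planted hydration sites
#'
#' Gaussian-scattered observations around each planted center plus
#' optional uniform noise in the surrounding box.
#'
#' @param spec a [fixture_spec()]; uses `site_centers`, `site_sigma`,
#'   `n_per_site`, `n_noise`, `seed`.
#' @return list: `observations` (matrix), `centers`, `assignment`
#'   (planted site of each observation, 0 for noise).
#' @export
make_site_fixture <- function(spec = fixture_spec()) {
  ctr <- as.matrix(spec$site_centers)
  k <- nrow(ctr)
  if (k > 1) {
    dmin <- min(stats::dist(ctr))
    if (dmin < 5 * spec$site_sigma)
      stop(sprintf("planted centers overlap: minimum separation %.2f < 5 * sigma = %.2f",
                   dmin, 5 * spec$site_sigma))
  }
  with_seed(spec$seed, {
    obs <- do.call(rbind, lapply(seq_len(k), function(i) {
      sweep(matrix(stats::rnorm(3 * spec$n_per_site, sd = spec$site_sigma),
                   ncol = 3), 2, ctr[i, ], `+`)
    }))
    assignment <- rep(seq_len(k), each = spec$n_per_site)
    if (spec$n_noise > 0) {
      lo <- apply(ctr, 2, min) - 10
      hi <- apply(ctr, 2, max) + 10
      noise <- vapply(1:3, function(j)
        stats::runif(spec$n_noise, lo[j], hi[j]), numeric(spec$n_noise))
      if (spec$n_noise == 1) noise <- matrix(noise, ncol = 3)
      obs <- rbind(obs, noise)
      assignment <- c(assignment, rep(0L, spec$n_noise))
    }
    list(observations = obs, centers = ctr, assignment = assignment)
  })
}
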