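# Density-based clustering of water-oxygen positions into hydration
# sites. Works on a single frame ("water clusters") or on observations
# pooled across frames ("favorable sites"); the two modes differ only in
# the observation pool.

#' Cluster water-oxygen observations into hydration sites
#'
#' DBSCAN-style density clustering: a core point has at least
#' `min_samples` observations (itself included) within `eps`; clusters
#' are the connected unions of core neighborhoods; non-core points within
#' `eps` of a core join the cluster of their nearest core point
#' (Euclidean ties broken by lower cluster index); everything else is
#' noise. Site centers are member centroids.
#'
#' @param x an n x 3 matrix of water-oxygen coordinates (Angstrom), or a
#'   `wb_structure`/`wb_trajectory` whose water oxygens are pooled over
#'   all frames.
#' @param eps neighborhood radius, Angstrom.
#' @param min_samples minimum neighborhood size of a core point.
#' @param n_frames frames the pool was drawn from (for the occupancy
#'   statistic); inferred when `x` is a structure or trajectory.
#' @param topology optional `wb_structure` used to report protein
#'   residues with a polar atom within `distWR` of each site center.
#' @param distWR residue-water interaction shell radius, Angstrom.
#' @return An object of class `wb_sites`: `sites` (data.frame: site, x,
#'   y, z, n_members, occupancy, spread, nearby_residues, sorted by
#'   descending n_members), `assignment` (0 = noise, else site id per
#'   observation) and `noise` (observation indices).
#' @export
cluster_waters <- function(x, eps = 1.0, min_samples = 4L, n_frames = NULL,
                           topology = NULL, distWR = 4.0) {
  if (eps <= 0) stop("eps must be positive")
  if (min_samples < 1) stop("min_samples must be at least 1")
  if (inherits(x, "wb_trajectory") || inherits(x, "wb_structure")) {
    topo <- as_topology(x)
    if (is.null(topology)) topology <- topo
    wo <- select_atoms(topo, "water-oxygen")
    nf <- dim(x$coords)[3]
    if (is.null(n_frames)) n_frames <- nf
    obs <- do.call(rbind, lapply(seq_len(nf), function(f)
      frame_coords(x, f)[wo, , drop = FALSE]))
  } else {
    obs <- as.matrix(x)
  }
  n_frames <- n_frames %||% 1L
  n <- nrow(obs)
  empty <- list(sites = data.frame(
    site = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
    n_members = integer(0), occupancy = numeric(0), spread = numeric(0),
    nearby_residues = character(0), stringsAsFactors = FALSE),
    assignment = integer(0), noise = integer(0))
  if (is.null(n) || n == 0)
    return(structure(empty, class = "wb_sites"))
  if (n == 1) {
    if (min_samples <= 1) {
      sites <- site_table(obs, rep(1L, 1), 1L, n_frames, topology, distWR)
      return(structure(list(sites = sites$tab, assignment = sites$assign,
                            noise = integer(0)), class = "wb_sites"))
    }
    empty$assignment <- 0L
    empty$noise <- 1L
    return(structure(empty, class = "wb_sites"))
  }

  nb <- neighbor_pairs(obs, eps)
  nb_list <- vector("list", n)
  for (r in seq_len(nrow(nb))) {
    nb_list[[nb$i[r]]] <- c(nb_list[[nb$i[r]]], nb$j[r])
    nb_list[[nb$j[r]]] <- c(nb_list[[nb$j[r]]], nb$i[r])
  }
  deg <- vapply(nb_list, length, integer(1))
  core <- which(deg + 1L >= min_samples)

  labels <- integer(n)            # 0 = unassigned/noise
  cl <- 0L
  for (p in core) {               # flood-fill over core-core adjacency
    if (labels[p] != 0L) next
    cl <- cl + 1L
    queue <- p
    labels[p] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (nbq in nb_list[[q]]) {
        if (nbq %in% core && labels[nbq] == 0L) {
          labels[nbq] <- cl
          queue <- c(queue, nbq)
        }
      }
    }
  }
  # border points: nearest core within eps, ties by lower cluster index
  border <- setdiff(which(deg > 0), core)
  for (p in border) {
    cores_nb <- intersect(nb_list[[p]], core)
    if (!length(cores_nb)) next
    d <- sqrt(colSums((t(obs[cores_nb, , drop = FALSE]) - obs[p, ])^2))
    best <- cores_nb[order(d, labels[cores_nb])][1]
    labels[p] <- labels[best]
  }

  if (cl == 0L)
    return(structure(list(sites = empty$sites, assignment = labels,
                          noise = which(labels == 0L)), class = "wb_sites"))

  st <- site_table(obs, labels, cl, n_frames, topology, distWR)
  structure(list(sites = st$tab, assignment = st$assign,
                 noise = which(st$assign == 0L)), class = "wb_sites")
}

site_table <- function(obs, labels, n_clusters, n_frames, topology,
                       distWR) {
  tabs <- lapply(seq_len(n_clusters), function(k) {
    idx <- which(labels == k)
    ctr <- colMeans(obs[idx, , drop = FALSE])
    spread <- sqrt(mean(rowSums(
      sweep(obs[idx, , drop = FALSE], 2, ctr)^2)))
    nearby <- ""
    if (!is.null(topology)) {
      pp <- select_atoms(topology, "protein-polar-heavy")
      if (length(pp)) {
        xyz <- frame_coords(topology, 1)
        d <- sqrt(colSums((t(xyz[pp, , drop = FALSE]) - ctr)^2))
        nearby <- paste(sort(unique(
          residue_ids(topology$atoms)[pp[d <= distWR]])), collapse = ",")
      }
    }
    data.frame(site = k, x = ctr[1], y = ctr[2], z = ctr[3],
               n_members = length(idx),
               occupancy = length(idx) / n_frames, spread = spread,
               nearby_residues = nearby, first_member = min(idx),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  ord <- order(-tab$n_members, tab$first_member)
  tab <- tab[ord, , drop = FALSE]
  relabel <- match(seq_len(n_clusters), tab$site)
  assign <- labels
  assign[labels != 0L] <- relabel[labels[labels != 0L]]
  tab$site <- seq_len(nrow(tab))
  tab$first_member <- NULL
  rownames(tab) <- NULL
  list(tab = tab, assign = assign)
}

#' @export
print.wb_sites <- function(x, ...) {
  cat(sprintf("<wb_sites> %d site(s), %d noise observation(s)\n",
              nrow(x$sites), length(x$noise)))
  if (nrow(x$sites)) print(utils::head(x$sites, 10))
  invisible(x)
}

#' Write hydration-site centers as PDB pseudo-atoms
#'
#' One HETATM per site, residue name DUM, atom name O, at the site
#' center; the occupancy column carries `min(occupancy, 1)` and the
#' B-factor column the site spread.
#'
#' @param sites a [cluster_waters()] result.
#' @param file optional output path.
#' @return PDB text (invisibly when `file` given). An empty site list
#'   yields a valid header-only file.
#' @export
write_site_centers <- function(sites, file = NULL) {
  tab <- sites$sites
  if (!nrow(tab)) {
    txt <- "REMARK   aquabridge hydration sites (none)\nEND"
    if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
    return(txt)
  }
  atoms <- data.frame(
    serial = tab$site, name = "O", element = "O", resname = "DUM",
    resnum = tab$site, chain = "X", insert = "", altloc = "",
    occupancy = pmin(tab$occupancy, 1), bfactor = tab$spread,
    stringsAsFactors = FALSE)
  s <- wb_structure(atoms, as.matrix(tab[, c("x", "y", "z")]))
  write_pdb(s, file = file)
}

#' Write the hydration-site table as CSV
#'
#' @param sites a [cluster_waters()] result.
#' @param file output path.
#' @export
write_site_table <- function(sites, file) {
  utils::write.csv(sites$sites, file, row.names = FALSE)
  invisible(file)
}
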