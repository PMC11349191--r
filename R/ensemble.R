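# Frame-wise bridge detection across an ensemble or trajectory, and the
# per-residue-pair aggregate statistics.

#' Analyze water bridges across an ensemble or trajectory
#'
#' Runs [hbond_graph()] + [chain_method()] on every selected frame and
#' aggregates per unordered residue pair: bridge frequency (fraction of
#' analyzed frames where the pair is bridged), endpoint-distance mean and
#' population standard deviation over bridged frames, mean number of
#' distinct bridging waters, and interaction duration as the longest and
#' mean run of consecutive bridged frames (also in ps when the trajectory
#' carries a timestep). A bridge's identity across frames is the residue
#' pair, so water exchange does not interrupt it.
#'
#' @param x a multi-frame `wb_structure` or a `wb_trajectory`.
#' @param criteria a [wb_criteria()].
#' @param stride analyze every `stride`-th frame.
#' @return An object of class `wb_ensemble`: `stats` (data.frame sorted by
#'   descending frequency), `per_frame` (list of per-frame bridge tables),
#'   `frames` (indices analyzed), `n_frames`, `timestep`, `criteria`, and
#'   `residues` (protein residue ids of the topology).
#' @export
analyze_ensemble <- function(x, criteria = wb_criteria(), stride = 1L) {
  if (stride < 1) stop("stride must be at least 1")
  topo <- as_topology(x)
  nf <- n_frames(x)
  frames <- seq.int(1L, nf, by = as.integer(stride))
  if (!length(frames)) stop("stride selects zero frames")
  timestep <- if (inherits(x, "wb_trajectory")) x$timestep else NULL

  struct_for <- function(f) {
    if (inherits(x, "wb_trajectory"))
      wb_structure(topo$atoms, x$coords[, , f, drop = FALSE],
                   water_names = criteria$water_names)
    else x
  }
  per_frame <- lapply(frames, function(f) {
    if (inherits(x, "wb_trajectory")) {
      g <- hbond_graph(struct_for(f), 1L, criteria)
      b <- chain_method(g, criteria)
      b$frame <- rep(f, nrow(b))
      b
    } else {
      chain_method(hbond_graph(x, f, criteria), criteria)
    }
  })
  names(per_frame) <- as.character(frames)

  all_b <- do.call(rbind, per_frame)
  prot <- topo$atoms[!topo$atoms$is_water & !topo$atoms$is_hydrogen, ,
                     drop = FALSE]
  residues <- unique(residue_ids(prot))
  stats <- aggregate_bridge_stats(all_b, length(frames), timestep, stride)
  structure(list(stats = stats, per_frame = per_frame, frames = frames,
                 n_frames = length(frames), timestep = timestep,
                 criteria = criteria, residues = residues),
            class = "wb_ensemble")
}

aggregate_bridge_stats <- function(all_b, n_total, timestep, stride) {
  empty <- data.frame(
    res_a = character(0), res_b = character(0), frequency = numeric(0),
    n_frames_present = integer(0), mean_distance = numeric(0),
    sd_distance = numeric(0), mean_waters = numeric(0),
    max_consecutive = integer(0), mean_run = numeric(0),
    max_consecutive_ps = numeric(0), stringsAsFactors = FALSE)
  if (is.null(all_b) || !nrow(all_b)) return(empty)
  key <- pair_key(all_b$res_a, all_b$res_b)
  frame_seq <- sort(unique(all_b$frame))
  rows <- lapply(split(seq_len(nrow(all_b)), key), function(idx) {
    b <- all_b[idx, , drop = FALSE]
    n_pres <- length(unique(b$frame))
    d <- b$distance_AB
    mu <- mean(d)
    sdp <- sqrt(mean((d - mu)^2))   # population SD; 0 for a single frame
    pres <- sort(unique(b$frame))
    runs <- run_lengths(pres, stride)
    data.frame(
      res_a = min(b$res_a[1], b$res_b[1]),
      res_b = max(b$res_a[1], b$res_b[1]),
      frequency = n_pres / n_total, n_frames_present = n_pres,
      mean_distance = mu, sd_distance = sdp,
      mean_waters = mean(b$n_waters),
      max_consecutive = max(runs), mean_run = mean(runs),
      max_consecutive_ps = if (!is.null(timestep))
        max(runs) * timestep * stride else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frequency, out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# lengths of maximal runs of consecutive analyzed frames
run_lengths <- function(present_frames, stride) {
  gaps <- diff(present_frames)
  brk <- c(0, which(gaps != stride), length(present_frames))
  diff(brk)
}

#' Symmetric residue-by-residue bridge frequency matrix
#'
#' @param stats the `stats` table of a [analyze_ensemble()] result (or the
#'   `wb_ensemble` itself).
#' @param residues ordered residue ids for the matrix axes; defaults to
#'   the ensemble's protein residues.
#' @param value which statistic to spread: `"frequency"`,
#'   `"mean_distance"` or `"mean_waters"`.
#' @return numeric matrix with residue ids as dimnames; symmetric, zero
#'   diagonal.
#' @export
frequency_matrix <- function(stats, residues = NULL, value = "frequency") {
  if (inherits(stats, "wb_ensemble")) {
    residues <- residues %||% stats$residues
    stats <- stats$stats
  }
  if (is.null(residues)) stop("a residue list is required")
  m <- matrix(0, length(residues), length(residues),
              dimnames = list(residues, residues))
  for (r in seq_len(nrow(stats))) {
    i <- match(stats$res_a[r], residues)
    j <- match(stats$res_b[r], residues)
    if (is.na(i) || is.na(j))
      stop(sprintf("stats pair %s -- %s is not in the residue list",
                   stats$res_a[r], stats$res_b[r]))
    m[i, j] <- m[j, i] <- stats[[value]][r]
  }
  m
}

#' Color-code a structure by bridge frequency
#'
#' Every atom of a residue that participates in at least one bridge
#' carries that residue's maximum bridge frequency; all other atoms carry
#' 0. Values are clamped to [0, 1] and intended for the PDB B-factor
#' column (0 = blue to 1 = red in standard viewers).
#'
#' @param structure a `wb_structure`.
#' @param stats a [analyze_ensemble()] result or its `stats` table.
#' @return The structure with an `override` element holding the per-atom
#'   values; pass it to [write_pdb()] as `bfactor_override`, or use
#'   `attr(, "override")` directly.
#' @export
color_code_structure <- function(structure, stats) {
  if (inherits(stats, "wb_ensemble")) stats <- stats$stats
  rid <- residue_ids(structure$atoms)
  per_res <- numeric(0)
  if (nrow(stats)) {
    for (r in seq_len(nrow(stats))) {
      for (res in c(stats$res_a[r], stats$res_b[r])) {
        per_res[res] <- max(per_res[res] %|NA|% 0, stats$frequency[r])
      }
    }
  }
  ov <- unname(per_res[rid])
  ov[is.na(ov)] <- 0
  structure$override <- pmin(pmax(ov, 0), 1)
  structure
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Per-frame presence/distance trace of one bridge
#'
#' @param ens a [analyze_ensemble()] result.
#' @param res_a,res_b residue ids of the pair (order irrelevant).
#' @param file optional TSV output path.
#' @return data.frame with one row per analyzed frame: `frame`, `present`,
#'   `distance_AB` (NA when absent) and `n_waters`.
#' @export
save_bridge_trace <- function(ens, res_a, res_b, file = NULL) {
  stopifnot(inherits(ens, "wb_ensemble"))
  if (!(res_a %in% ens$residues) || !(res_b %in% ens$residues))
    stop(sprintf("unknown residue pair: %s -- %s", res_a, res_b))
  key <- pair_key(res_a, res_b)
  rows <- lapply(seq_along(ens$frames), function(k) {
    b <- ens$per_frame[[k]]
    hit <- if (nrow(b)) which(pair_key(b$res_a, b$res_b) == key) else integer(0)
    data.frame(frame = ens$frames[k], present = length(hit) > 0,
               distance_AB = if (length(hit)) b$distance_AB[hit[1]] else NA_real_,
               n_waters = if (length(hit)) b$n_waters[hit[1]] else 0L)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# aquabridge %s; pair %s -- %s",
                       as.character(utils::packageVersion("aquabridge")),
                       res_a, res_b), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Write a frequency (or other statistic) matrix as CSV
#'
#' @param m a [frequency_matrix()] result.
#' @param file output path.
#' @export
write_matrix_csv <- function(m, file) {
  utils::write.csv(as.data.frame(m), file)
  invisible(file)
}
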