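# Chain method: residue pairs connected through chains of <= maxDepth
# waters. Cluster method: connected water/residue components. Both operate
# on the hydrogen-bond graph of a single frame.

# Undirected adjacency lists over {protein polar atoms, water oxygens},
# protein-protein edges excluded (they are not bridge edges).
bridge_adjacency <- function(graph) {
  e <- graph$edges[graph$edges$kind != "protein-protein", , drop = FALSE]
  if (!nrow(e)) return(list(adj = list(), verts = integer(0)))
  u <- unique(data.frame(x = pmin(e$donor, e$acceptor),
                         y = pmax(e$donor, e$acceptor)))
  adj <- list()
  addl <- function(adj, from, to) {
    k <- as.character(from)
    adj[[k]] <- c(adj[[k]], to)
    adj
  }
  for (r in seq_len(nrow(u))) {
    adj <- addl(adj, u$x[r], u$y[r])
    adj <- addl(adj, u$y[r], u$x[r])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  list(adj = adj, verts = sort(unique(c(u$x, u$y))))
}

#' Find water bridges between residue pairs (Chain method)
#'
#' Enumerates, for every protein polar atom, all simple paths whose
#' interior vertices are exclusively water molecules, up to
#' `criteria$maxDepth` waters deep. Every unordered pair of protein
#' residues connected by at least one such path yields one bridge row
#' carrying the shortest qualifying water path (ties broken by
#' lexicographically smallest water residue identifiers) and the count of
#' distinct waters seen in any qualifying path. Direct protein-protein
#' hydrogen bonds are not bridges.
#'
#' @param graph a [hbond_graph()] result.
#' @param criteria a [wb_criteria()]; defaults to the graph's own.
#' @return data.frame, one row per unordered residue pair: residue and
#'   atom labels for both endpoints, `depth`, `water_path`
#'   (comma-separated ids of the retained path), `n_waters` (distinct
#'   waters over all qualifying paths), `distance_AB` (Angstrom between
#'   the two endpoint heavy atoms) and `frame`.
#' @export
chain_method <- function(graph, criteria = graph$criteria) {
  s <- graph$structure
  a <- s$atoms
  xyz <- frame_coords(s, graph$frame)
  rid <- residue_ids(a)
  ba <- bridge_adjacency(graph)
  empty <- data.frame(
    res_a = character(0), atom_a = character(0), res_b = character(0),
    atom_b = character(0), depth = integer(0), water_path = character(0),
    n_waters = integer(0), distance_AB = numeric(0), frame = integer(0),
    stringsAsFactors = FALSE)
  if (!length(ba$verts)) return(empty)
  wat <- a$is_water
  prot_verts <- ba$verts[!wat[ba$verts]]

  found <- new.env(parent = emptyenv())
  record <- function(p, q, path) {
    key <- pair_key(rid[p], rid[q])
    cur <- get0(key, envir = found)
    cand <- list(p = p, q = q, path = path)
    found[[key]] <- c(cur, list(cand))
  }
  for (p in prot_verts) {
    adj_p <- ba$adj[[as.character(p)]]
    wstart <- adj_p[wat[adj_p]]
    enum <- function(w, path) {
      for (q in ba$adj[[as.character(w)]]) {
        if (!wat[q] && q != p &&
            (rid[q] != rid[p] || criteria$include_intra_residue))
          record(p, q, path)
      }
      if (length(path) < criteria$maxDepth) {
        for (w2 in ba$adj[[as.character(w)]])
          if (wat[w2] && !(w2 %in% path)) enum(w2, c(path, w2))
      }
    }
    for (w in wstart) enum(w, w)
  }

  keys <- sort(ls(found))
  if (!length(keys)) return(empty)
  rows <- lapply(keys, function(key) {
    cands <- get(key, envir = found)
    depths <- vapply(cands, function(cc) length(cc$path), integer(1))
    dmin <- min(depths)
    best <- cands[depths == dmin]
    pstr <- vapply(best, function(cc)
      paste(rid[cc$path], collapse = ","), character(1))
    # order endpoints canonically, then pick lexicographically smallest path
    estr <- vapply(best, function(cc)
      paste(sort(c(paste(rid[cc$p], a$name[cc$p]),
                   paste(rid[cc$q], a$name[cc$q]))), collapse = "|"),
      character(1))
    pick <- best[[order(pstr, estr)[1]]]
    p <- pick$p; q <- pick$q
    if (rid[q] < rid[p]) { tmp <- p; p <- q; q <- tmp }
    all_w <- unique(unlist(lapply(cands, function(cc) cc$path)))
    data.frame(
      res_a = rid[p], atom_a = trimws(a$name[p]),
      res_b = rid[q], atom_b = trimws(a$name[q]),
      depth = dmin,
      water_path = paste(rid[pick$path], collapse = ","),
      n_waters = length(all_w),
      distance_AB = vec_norm(xyz[p, ] - xyz[q, ]),
      frame = graph$frame, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find water/residue clusters (Cluster method)
#'
#' Connected components of the subgraph induced by water-water and
#' protein-water hydrogen bonds. Water membership is truncated at
#' `maxDepth` water hops from the nearest protein-bonded water; components
#' containing no protein contact at all are reported as bulk clusters with
#' `n_residues` 0.
#'
#' @inheritParams chain_method
#' @return data.frame, one row per cluster: `waters` and `residues`
#'   (comma-separated ids), `n_waters`, `n_residues`, `frame`; sorted by
#'   descending `n_waters`.
#' @export
cluster_method <- function(graph, criteria = graph$criteria) {
  s <- graph$structure
  a <- s$atoms
  rid <- residue_ids(a)
  ba <- bridge_adjacency(graph)
  empty <- data.frame(waters = character(0), residues = character(0),
                      n_waters = integer(0), n_residues = integer(0),
                      frame = integer(0), stringsAsFactors = FALSE)
  if (!length(ba$verts)) return(empty)
  wat <- a$is_water
  waters <- ba$verts[wat[ba$verts]]
  prot <- ba$verts[!wat[ba$verts]]

  # water depth = hops to nearest protein-bonded water (that water = 1)
  depth <- setNames(rep(Inf, length(waters)), waters)
  frontier <- waters[vapply(waters, function(w)
    any(!wat[ba$adj[[as.character(w)]]]), logical(1))]
  depth[as.character(frontier)] <- 1
  d <- 1
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(w) {
      nb <- ba$adj[[as.character(w)]]
      nb[wat[nb]]
    })))
    nxt <- nxt[is.infinite(depth[as.character(nxt)])]
    if (!length(nxt)) break
    d <- d + 1
    depth[as.character(nxt)] <- d
    frontier <- nxt
  }
  keep_w <- waters[depth[as.character(waters)] <= criteria$maxDepth |
                     is.infinite(depth[as.character(waters)])]
  verts <- c(keep_w, prot)

  # union-find over the induced subgraph
  parent <- setNames(verts, verts)
  findr <- function(x) {
    x <- as.character(x)
    while (parent[[x]] != as.numeric(x)) x <- as.character(parent[[x]])
    as.numeric(x)
  }
  unite <- function(x, y) {
    rx <- findr(x); ry <- findr(y)
    if (rx != ry) parent[[as.character(max(rx, ry))]] <<- min(rx, ry)
  }
  for (v in keep_w) {
    for (nb in ba$adj[[as.character(v)]]) {
      if ((wat[nb] && nb %in% keep_w) || !wat[nb]) unite(v, nb)
    }
  }
  roots <- vapply(verts, findr, numeric(1))
  comp <- split(verts, roots)
  rows <- lapply(comp, function(vs) {
    ws <- vs[wat[vs]]
    if (!length(ws)) return(NULL)
    rs <- sort(unique(rid[vs[!wat[vs]]]))
    wids <- sort(unique(rid[ws]))
    data.frame(waters = paste(wids, collapse = ","),
               residues = paste(rs, collapse = ","),
               n_waters = length(wids), n_residues = length(rs),
               frame = graph$frame, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_waters, out$waters), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate bridges to unordered residue pairs
#'
#' @param bridges a [chain_method()] result (possibly several rbind-ed
#'   frames).
#' @return data.frame keyed by unordered pair: minimal `depth` and
#'   `n_waters`, the number of distinct waters in any qualifying path.
#' @export
bridges_to_residue_pairs <- function(bridges) {
  empty <- data.frame(res_a = character(0), res_b = character(0),
                      depth = integer(0), n_waters = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(bridges)) return(empty)
  key <- pair_key(bridges$res_a, bridges$res_b)
  rows <- lapply(split(seq_len(nrow(bridges)), key), function(idx) {
    waters <- unique(unlist(strsplit(bridges$water_path[idx], ",")))
    nw <- max(bridges$n_waters[idx], length(waters))
    data.frame(res_a = min(bridges$res_a[idx[1]], bridges$res_b[idx[1]]),
               res_b = max(bridges$res_a[idx[1]], bridges$res_b[idx[1]]),
               depth = min(bridges$depth[idx]), n_waters = nw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[sort(names(rows))])
  rownames(out) <- NULL
  out
}

#' Write a bridge table as TSV
#'
#' One row per bridge: frame, endpoint chain/residue/atom labels, depth,
#' water ids and the endpoint distance in Angstrom (2 decimals). A header
#' comment line records the package version and resolved criteria.
#'
#' @param bridges a [chain_method()] result.
#' @param file output path.
#' @param criteria optional criteria echoed in the header.
#' @export
write_bridge_table <- function(bridges, file, criteria = NULL) {
  hdr <- sprintf("# aquabridge %s%s",
                 as.character(utils::packageVersion("aquabridge")),
                 if (!is.null(criteria))
                   paste0("; ", paste(format_criteria(criteria),
                                      collapse = "; ")) else "")
  split_id <- function(x) {
    parts <- strsplit(x, ":", fixed = TRUE)
    list(chain = vapply(parts, `[`, "", 1),
         res = vapply(parts, function(p) paste(p[2], p[3]), ""))
  }
  a <- split_id(bridges$res_a); b <- split_id(bridges$res_b)
  tab <- data.frame(frame = bridges$frame, chainA = a$chain, resA = a$res,
                    atomA = bridges$atom_a, chainB = b$chain, resB = b$res,
                    atomB = bridges$atom_b, depth = bridges$depth,
                    waters = bridges$water_path,
                    distance_AB = sprintf("%.2f", bridges$distance_AB),
                    stringsAsFactors = FALSE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
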