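# Independent oracles used to cross-check the package's algorithms.
# They share no code with the implementation: path enumeration goes
# through igraph, density clustering through exhaustive dist() matrices.

# Build a synthetic hydrogen-bond graph object (the contract chain_method
# consumes) from an explicit undirected edge list over protein polar
# atoms and waters, plus the matching igraph for the oracle.
random_bridge_graph <- function(n_prot, n_wat, p_pw, p_ww, seed,
                                criteria = wb_criteria()) {
  set.seed(seed)
  n <- n_prot + n_wat
  atoms <- data.frame(
    serial = seq_len(n), name = "O", element = "O",
    resname = c(rep("GLY", n_prot), rep("HOH", n_wat)),
    resnum = c(seq_len(n_prot), 100L + seq_len(n_wat)),
    chain = c(rep("A", n_prot), rep("W", n_wat)),
    insert = "", altloc = "", occupancy = 1, bfactor = 0,
    stringsAsFactors = FALSE)
  s <- wb_structure(atoms, matrix(runif(3 * n, 0, 20), ncol = 3))
  is_w <- s$atoms$is_water
  edges <- list(); k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is_w[i] && !is_w[j]) next          # protein-protein: not an edge
    p <- if (is_w[i] && is_w[j]) p_ww else p_pw
    if (runif(1) < p) {
      k <- k + 1
      edges[[k]] <- data.frame(
        donor = i, hydrogen = NA_integer_, acceptor = j,
        distance = runif(1, 2.5, 3.5), angle = NA_real_,
        kind = if (is_w[i] && is_w[j]) "water-water" else "protein-water",
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), distance = numeric(0),
               angle = numeric(0), kind = character(0))
  g <- structure(list(edges = edges, frame = 1L, criteria = criteria,
                      roles = rep("both", n), angle_mode = "angle-free",
                      structure = s),
                 class = "wb_hbond_graph")
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) data.frame(from = edges$donor, to = edges$acceptor)
        else data.frame(from = integer(0), to = integer(0)),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  list(graph = g, igraph = ig, is_water = is_w, n_prot = n_prot,
       structure = s)
}

# Exhaustive enumeration of residue pairs linked by a simple path whose
# interior vertices are all waters, with 1..max_depth interior waters.
oracle_bridged_pairs <- function(rg, max_depth) {
  found <- character(0)
  prot <- which(!rg$is_water)
  rid <- aquabridge:::residue_ids(rg$structure$atoms)
  for (ii in seq_along(prot)) {
    for (jj in seq_along(prot)) {
      if (jj <= ii) next
      p <- prot[ii]; q <- prot[jj]
      paths <- igraph::all_simple_paths(rg$igraph, from = as.character(p),
                                        to = as.character(q),
                                        cutoff = max_depth + 1)
      for (pa in paths) {
        v <- as.integer(names(pa))
        interior <- v[-c(1, length(v))]
        if (length(interior) >= 1 && length(interior) <= max_depth &&
            all(rg$is_water[interior])) {
          found <- c(found, paste(sort(c(rid[p], rid[q])), collapse = "--"))
          break
        }
      }
    }
  }
  sort(unique(found))
}

pairs_of <- function(bridges) {
  if (!nrow(bridges)) return(character(0))
  sort(unique(ifelse(bridges$res_a < bridges$res_b,
                     paste(bridges$res_a, bridges$res_b, sep = "--"),
                     paste(bridges$res_b, bridges$res_a, sep = "--"))))
}

# Reference density clustering by exhaustive neighbor enumeration:
# core points from the full distance matrix, clusters as igraph
# components of the core-core adjacency, border points joined to the
# nearest core (ties by lower cluster index after relabeling by size).
oracle_density_partition <- function(obs, eps, min_samples) {
  n <- nrow(obs)
  dm <- as.matrix(dist(obs))
  nbr <- dm <= eps
  core <- which(rowSums(nbr) >= min_samples)   # row includes self
  labels <- integer(n)
  if (length(core)) {
    sub <- nbr[core, core, drop = FALSE]
    ig <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(ig)$membership
    labels[core] <- comp
    for (p in setdiff(seq_len(n), core)) {
      cands <- core[nbr[p, core]]
      if (length(cands)) {
        best <- cands[order(dm[p, cands], labels[cands])][1]
        labels[p] <- labels[best]
      }
    }
  }
  labels
}

# Compare two clusterings as partitions (label-permutation invariant);
# noise (0) must match exactly.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  key_a <- match(a, unique(a[a != 0]))
  key_b <- match(b, unique(b[b != 0]))
  identical(key_a, key_b)
}

# All-pairs brute force neighbor search (oracle for the cell list).
brute_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- list(); k <- 0
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) { k <- k + 1; out[[k]] <- c(i, j) }
  }
  if (!k) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}
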