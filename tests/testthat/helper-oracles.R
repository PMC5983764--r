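# Independent brute-force oracles. These re-derive every criterion from its
# definition with naive loops, deliberately sharing no code with the package
# internals, so that detector/community results can be checked against them.

# --- snapshot construction from a compact atom table -------------------------
# atoms: data.frame-ish with resno, res, name, element, x, y, z
make_snap <- function(resno, res, name, element, x, y, z, chain = "A") {
  n <- length(resno)
  atoms <- data.frame(
    eleno = seq_len(n), atom_name = as.character(name),
    element = as.character(element), altloc = rep("", n),
    res_name = as.character(res), chain = rep(chain, length.out = n),
    seq_index = as.integer(resno),
    x = x, y = y, z = z, occupancy = rep(1, n),
    is_hydrogen = element %in% c("H", "D"), is_het = rep(FALSE, n),
    key = rinpab::residue_key(rep(chain, length.out = n), resno),
    stringsAsFactors = FALSE)
  structure(list(model_index = 1L, atoms = atoms), class = "Snapshot")
}

# two-residue snapshot with one atom each, at a given separation along x
two_atom_snap <- function(res1, name1, ele1, res2, name2, ele2, d) {
  make_snap(resno = c(1, 2), res = c(res1, res2), name = c(name1, name2),
            element = c(ele1, ele2), x = c(0, d), y = c(0, 0), z = c(0, 0))
}

edist <- function(p, q) sqrt(sum((p - q)^2))

atom_mat <- function(s) {
  a <- s$atoms[!s$atoms$is_hydrogen, , drop = FALSE]
  a
}

# --- naive all-pairs detector scans ------------------------------------------
# each returns a sorted character vector of "key1|key2" residue pairs

pair_id <- function(k1, k2) paste(pmin(k1, k2), pmax(k1, k2), sep = "|")

oracle_hbond_pairs <- function(s, cutoff = 3.5) {
  a <- atom_mat(s)
  donors <- list(ALL = "N", SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2",
                 GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"), TRP = "NE1")
  acceptors <- list(ALL = c("O", "OXT"), SER = "OG", THR = "OG1", TYR = "OH",
                    ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
                    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  is_in <- function(i, tab) {
    a$atom_name[i] %in% tab$ALL ||
      (!is.null(tab[[a$res_name[i]]]) &&
         a$atom_name[i] %in% tab[[a$res_name[i]]])
  }
  out <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (a$key[i] == a$key[j]) next
      if (!a$element[i] %in% c("N", "O") || !a$element[j] %in% c("N", "O")) next
      if (!is_in(i, donors) || !is_in(j, acceptors)) next
      d <- edist(c(a$x[i], a$y[i], a$z[i]), c(a$x[j], a$y[j], a$z[j]))
      if (d <= cutoff) out <- c(out, pair_id(a$key[i], a$key[j]))
    }
  }
  sort(unique(out))
}

oracle_vdw_pairs <- function(s, cutoff = 0.5,
                             radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)) {
  a <- atom_mat(s)
  a <- a[a$element %in% names(radii), , drop = FALSE]
  out <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (j <= i || a$key[i] == a$key[j]) next
      d <- edist(c(a$x[i], a$y[i], a$z[i]), c(a$x[j], a$y[j], a$z[j]))
      if (d - radii[[a$element[i]]] - radii[[a$element[j]]] <= cutoff) {
        out <- c(out, pair_id(a$key[i], a$key[j]))
      }
    }
  }
  sort(unique(out))
}

oracle_ssbond_pairs <- function(s, cutoff = 2.5) {
  a <- atom_mat(s)
  a <- a[a$res_name == "CYS" & a$atom_name == "SG", , drop = FALSE]
  out <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (j <= i) next
      d <- edist(c(a$x[i], a$y[i], a$z[i]), c(a$x[j], a$y[j], a$z[j]))
      if (d <= cutoff) out <- c(out, pair_id(a$key[i], a$key[j]))
    }
  }
  sort(unique(out))
}

# mass-weighted group center over the atoms present
oracle_center <- function(a, idx, weighted = TRUE) {
  mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  w <- if (weighted) mass[a$element[idx]] else rep(1, length(idx))
  w <- w / sum(w)
  c(sum(a$x[idx] * w), sum(a$y[idx] * w), sum(a$z[idx] * w))
}

oracle_ionic_pairs <- function(s, cutoff = 4.0) {
  a <- atom_mat(s)
  pos_def <- list(ARG = c("CZ", "NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  neg_def <- list(ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"))
  centers <- function(def) {
    out <- list()
    for (k in unique(a$key)) {
      res <- a$res_name[a$key == k][1]
      if (is.null(def[[res]])) next
      idx <- which(a$key == k & a$atom_name %in% def[[res]])
      if (length(idx)) out[[k]] <- oracle_center(a, idx)
    }
    out
  }
  pos <- centers(pos_def); neg <- centers(neg_def)
  out <- character()
  for (kp in names(pos)) for (kn in names(neg)) {
    if (kp != kn && edist(pos[[kp]], neg[[kn]]) <= cutoff) {
      out <- c(out, pair_id(kp, kn))
    }
  }
  sort(unique(out))
}

oracle_ring_centers <- function(s) {
  a <- atom_mat(s)
  defs <- list(PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
               TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
               TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
               HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")))
  out <- list()
  for (k in unique(a$key)) {
    res <- a$res_name[a$key == k][1]
    if (is.null(defs[[res]])) next
    for (ring in defs[[res]]) {
      idx <- which(a$key == k & a$atom_name %in% ring)
      if (length(idx) == length(ring)) {
        out[[length(out) + 1L]] <- list(key = k,
                                        c = oracle_center(a, idx, FALSE))
      }
    }
  }
  out
}

oracle_pipi_pairs <- function(s, cutoff = 6.5) {
  rc <- oracle_ring_centers(s)
  out <- character()
  for (i in seq_along(rc)) for (j in seq_along(rc)) {
    if (j <= i || rc[[i]]$key == rc[[j]]$key) next
    if (edist(rc[[i]]$c, rc[[j]]$c) <= cutoff) {
      out <- c(out, pair_id(rc[[i]]$key, rc[[j]]$key))
    }
  }
  sort(unique(out))
}

oracle_pication_pairs <- function(s, cutoff = 5.0) {
  a <- atom_mat(s)
  rc <- oracle_ring_centers(s)
  cat_def <- list(ARG = c("CZ", "NE", "NH1", "NH2"), LYS = "NZ")
  out <- character()
  for (k in unique(a$key)) {
    res <- a$res_name[a$key == k][1]
    if (is.null(cat_def[[res]])) next
    idx <- which(a$key == k & a$atom_name %in% cat_def[[res]])
    if (!length(idx)) next
    cc <- oracle_center(a, idx)
    for (r in rc) {
      if (r$key != k && edist(cc, r$c) <= cutoff) {
        out <- c(out, pair_id(k, r$key))
      }
    }
  }
  sort(unique(out))
}

edge_pairs <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(unique(paste(edges$a, edges$b, sep = "|")))
}

# --- brute-force clique percolation oracle -----------------------------------
# enumerate all k-subsets, keep complete ones, connect cliques sharing k-1
# nodes, take connected components of that clique-overlap graph
cpm_oracle <- function(g, k = 3) {
  nm <- sort(igraph::V(g)$name)
  if (length(nm) < k) return(list())
  subsets <- utils::combn(nm, k, simplify = FALSE)
  cliq <- Filter(function(s) {
    prs <- utils::combn(s, 2)
    all(apply(prs, 2, function(p) igraph::are_adjacent(g, p[1], p[2])))
  }, subsets)
  if (!length(cliq)) return(list())
  n <- length(cliq)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i != j && length(intersect(cliq[[i]], cliq[[j]])) == k - 1
  }
  og <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(og)$membership
  comms <- lapply(split(seq_len(n), comp),
                  function(ix) sort(unique(unlist(cliq[ix]))))
  names(comms) <- NULL
  comms[order(vapply(comms, paste, "", collapse = "\r"))]
}

# breadth-first-search shortest path oracle
bfs_distance <- function(g, a, b) {
  if (a == b) return(0L)
  nm <- igraph::V(g)$name
  dist <- stats::setNames(rep(Inf, length(nm)), nm)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in igraph::neighbors(g, v)$name) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1L
        if (w == b) return(as.integer(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  Inf
}
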