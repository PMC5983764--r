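# ---- atom typing tables -----------------------------------------------------
# hydrogen-bond capable heavy atoms: standard backbone/side-chain assignments.
# Backbone N donates (its amide H is implicit), backbone O (and OXT) accepts;
# hydroxyls (Ser/Thr/Tyr) both donate and accept; His ring nitrogens both.

.hb_donor <- list(
  "*"   = "N",
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"), TRP = "NE1"
)
.hb_acceptor <- list(
  "*"   = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# charged groups: mass centers over the atoms present
.pos_groups <- list(
  ARG = c("CZ", "NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.neg_groups <- list(
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2")
)

# aromatic rings (geometric centers); Trp contributes both of its rings
.rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
)

.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# lean heavy-atom view of a snapshot: plain vectors + coordinate matrix.
# All detector cores work on this; it is computed once per network build.
prep_atoms <- function(s) {
  a <- s$atoms
  keep <- !a$is_hydrogen
  list(name = a$atom_name[keep], element = a$element[keep],
       res = a$res_name[keep], key = a$key[keep], eleno = a$eleno[keep],
       xyz = cbind(a$x[keep], a$y[keep], a$z[keep]),
       n = sum(keep))
}

# cross-distance matrix between coordinate matrices (rows = points)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

edge_df <- function(a = character(), b = character(), itype = character(),
                    distance = numeric(), energy = numeric()) {
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  out <- list(a = a, b = b, itype = itype, distance = distance,
              energy = energy)
  attr(out, "row.names") <- seq_along(a)
  class(out) <- "data.frame"
  out
}

match_atoms <- function(at, table) {
  hit <- if (!is.null(table[["*"]])) at$name %in% table[["*"]] else
    rep(FALSE, at$n)
  for (res in setdiff(names(table), "*")) {
    hit <- hit | (at$res == res & at$name %in% table[[res]])
  }
  hit
}

# keep, per unordered residue pair, the hit with minimal distance
min_per_pair <- function(keys_a, keys_b, d) {
  pair <- paste(pmin(keys_a, keys_b), pmax(keys_a, keys_b))
  ord <- order(pair, d)
  keep <- ord[!duplicated(pair[ord])]
  sort(keep)
}

# ---- detector cores ---------------------------------------------------------

hbond_core <- function(at, p) {
  di <- which(match_atoms(at, .hb_donor) & at$element %in% c("N", "O"))
  ai <- which(match_atoms(at, .hb_acceptor) & at$element %in% c("N", "O"))
  if (!length(di) || !length(ai)) return(edge_df())
  d <- cross_dist(at$xyz[di, , drop = FALSE], at$xyz[ai, , drop = FALSE])
  hit <- which(d <= p$hbond_cutoff &
                 outer(at$key[di], at$key[ai], "!="), arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  # dedup unordered atom pairs (hydroxyl-hydroxyl pairs match in both roles)
  e1 <- at$eleno[di[hit[, 1]]]; e2 <- at$eleno[ai[hit[, 2]]]
  keep <- !duplicated(paste(pmin(e1, e2), pmax(e1, e2)))
  hit <- hit[keep, , drop = FALSE]
  dist <- d[hit]
  edge_df(at$key[di[hit[, 1]]], at$key[ai[hit[, 2]]],
          rep("hbond", nrow(hit)), dist, hbond_energy(dist, p$energies))
}

vdw_core <- function(at, p) {
  known <- at$element %in% names(p$vdw_radii)
  if (any(!known)) {
    warning("skipping atoms with unknown vdW radius for element(s): ",
            paste(unique(at$element[!known]), collapse = ", "), call. = FALSE)
  }
  idx <- which(known)
  if (length(idx) < 2L) return(edge_df())
  r <- p$vdw_radii[at$element[idx]]
  d <- cross_dist(at$xyz[idx, , drop = FALSE], at$xyz[idx, , drop = FALSE])
  gap <- d - outer(r, r, "+")
  keys <- at$key[idx]
  hit <- which(gap <= p$vdw_surface_cutoff & outer(keys, keys, "<"),
               arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  ka <- keys[hit[, 1]]; kb <- keys[hit[, 2]]; g <- gap[hit]
  keep <- min_per_pair(ka, kb, g)
  edge_df(ka[keep], kb[keep], rep("vdw", length(keep)), g[keep],
          rep(p$energies$vdw, length(keep)))
}

ssbond_core <- function(at, p) {
  sg <- which(at$res == "CYS" & at$name == "SG")
  if (length(sg) < 2L) return(edge_df())
  d <- cross_dist(at$xyz[sg, , drop = FALSE], at$xyz[sg, , drop = FALSE])
  keys <- at$key[sg]
  hit <- which(d <= p$ssbond_cutoff & outer(keys, keys, "<"), arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  edge_df(keys[hit[, 1]], keys[hit[, 2]], rep("ssbond", nrow(hit)), d[hit],
          rep(p$energies$ssbond, nrow(hit)))
}

# mass-weighted centers of the named atom groups; one row per residue that
# has at least one group atom present
group_centers <- function(at, groups) {
  keys <- character(); xyz <- list()
  for (res in names(groups)) {
    sel <- which(at$res == res & at$name %in% groups[[res]])
    if (!length(sel)) next
    for (k in unique(at$key[sel])) {
      i <- sel[at$key[sel] == k]
      m <- .atomic_mass[at$element[i]]
      m[is.na(m)] <- 12
      w <- m / sum(m)
      keys <- c(keys, k)
      xyz[[length(xyz) + 1L]] <- colSums(at$xyz[i, , drop = FALSE] * w)
    }
  }
  list(key = keys, xyz = if (length(xyz)) do.call(rbind, xyz) else
    matrix(numeric(), 0, 3))
}

# geometric centers of aromatic rings; incomplete rings skipped with warning
ring_centers <- function(at, his_aromatic = TRUE) {
  rings <- .rings
  if (!his_aromatic) rings$HIS <- NULL
  keys <- character(); xyz <- list(); skipped <- character()
  aro <- which(at$res %in% names(rings))
  for (k in unique(at$key[aro])) {
    i <- aro[at$key[aro] == k]
    res <- at$res[i[1]]
    for (ring in rings[[res]]) {
      j <- i[match(ring, at$name[i])]
      if (anyNA(j)) {
        skipped <- c(skipped, k)
        next
      }
      keys <- c(keys, k)
      xyz[[length(xyz) + 1L]] <- colMeans(at$xyz[j, , drop = FALSE])
    }
  }
  if (length(skipped)) {
    warning("incomplete aromatic ring(s) skipped: ",
            paste(format_residue_key(unique(skipped)), collapse = ", "),
            call. = FALSE)
  }
  list(key = keys, xyz = if (length(xyz)) do.call(rbind, xyz) else
    matrix(numeric(), 0, 3))
}

ionic_core <- function(at, p) {
  posg <- .pos_groups
  if (!p$his_cationic) posg$HIS <- NULL
  pos <- group_centers(at, posg)
  neg <- group_centers(at, .neg_groups)
  if (!length(pos$key) || !length(neg$key)) return(edge_df())
  d <- cross_dist(pos$xyz, neg$xyz)
  hit <- which(d <= p$ionic_cutoff & outer(pos$key, neg$key, "!="),
               arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  edge_df(pos$key[hit[, 1]], neg$key[hit[, 2]], rep("ionic", nrow(hit)),
          d[hit], rep(p$energies$ionic, nrow(hit)))
}

pipi_core <- function(at, p) {
  rc <- ring_centers(at, p$his_aromatic)
  if (length(rc$key) < 2L) return(edge_df())
  d <- cross_dist(rc$xyz, rc$xyz)
  hit <- which(d <= p$pipi_cutoff & outer(rc$key, rc$key, "<"),
               arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  ka <- rc$key[hit[, 1]]; kb <- rc$key[hit[, 2]]; dd <- d[hit]
  keep <- min_per_pair(ka, kb, dd)
  edge_df(ka[keep], kb[keep], rep("pipi", length(keep)), dd[keep],
          rep(p$energies$pipi, length(keep)))
}

pication_core <- function(at, p) {
  cats <- group_centers(at, .pos_groups[c("ARG", "LYS")])
  rc <- ring_centers(at, p$his_aromatic)
  if (!length(cats$key) || !length(rc$key)) return(edge_df())
  d <- cross_dist(cats$xyz, rc$xyz)
  hit <- which(d <= p$pication_cutoff & outer(cats$key, rc$key, "!="),
               arr.ind = TRUE)
  if (!nrow(hit)) return(edge_df())
  ka <- cats$key[hit[, 1]]; kb <- rc$key[hit[, 2]]; dd <- d[hit]
  keep <- min_per_pair(ka, kb, dd)
  edge_df(ka[keep], kb[keep], rep("pication", length(keep)), dd[keep],
          rep(p$energies$pication, length(keep)))
}

# ---- exported detectors -----------------------------------------------------

#' Detect hydrogen bonds
#'
#' A hydrogen bond is recorded between a donor-capable heavy atom (N/O with an
#' implicit hydrogen) of one residue and an acceptor-capable heavy atom (N/O)
#' of another residue whenever their distance is at most `p$hbond_cutoff`
#' (default 3.5 A). No explicit-hydrogen geometry or angle term is used: the
#' criterion is the heavy-atom donor-acceptor distance. One edge per
#' donor/acceptor atom pair (deduplicated when both atoms can play both
#' roles).
#'
#' @param s a [Snapshot][read_structure].
#' @param p [interaction_params()].
#' @return data.frame of interaction edges: residue keys `a`, `b` (unordered,
#'   stored sorted), `itype`, `distance` (A), `energy` (kJ/mol annotation).
#' @export
find_hbonds <- function(s, p = interaction_params()) {
  hbond_core(prep_atoms(s), p)
}

#' Detect van der Waals contacts
#'
#' Two residues are in van der Waals contact when the minimum over their
#' heavy-atom pairs of the surface gap (center distance minus the two Bondi
#' radii) is at most `p$vdw_surface_cutoff` (default 0.5 A). The reported
#' `distance` is that surface gap (it may be negative for interpenetrating
#' atoms). Atoms whose element has no radius in `p$vdw_radii` are skipped with
#' a warning.
#'
#' @inheritParams find_hbonds
#' @return data.frame of interaction edges (one per residue pair).
#' @export
find_vdw <- function(s, p = interaction_params()) {
  vdw_core(prep_atoms(s), p)
}

#' Detect disulfide bonds
#'
#' Cysteine SG-SG pairs at distance at most `p$ssbond_cutoff` (default 2.5 A).
#' Sulfurs of other residues (e.g. Met SD) never form this edge type.
#'
#' @inheritParams find_hbonds
#' @return data.frame of interaction edges.
#' @export
find_disulfide <- function(s, p = interaction_params()) {
  ssbond_core(prep_atoms(s), p)
}

#' Detect ionic interactions
#'
#' An ionic edge links one positively charged group (Arg guanidinium, Lys
#' ammonium, optionally His imidazole) and one negatively charged group
#' (Asp/Glu carboxylate) whose mass centers are at most `p$ionic_cutoff`
#' apart (default 4.0 A). Same-sign pairs are never edges.
#'
#' @inheritParams find_hbonds
#' @return data.frame of interaction edges.
#' @export
find_ionic <- function(s, p = interaction_params()) {
  ionic_core(prep_atoms(s), p)
}

#' Detect pi-pi stacking
#'
#' Aromatic ring geometric centers (Phe, Tyr, His; both Trp rings, the closest
#' pair of centers is used) at most `p$pipi_cutoff` apart (default 6.5 A).
#' Residues with incomplete rings are skipped with a warning.
#'
#' @inheritParams find_hbonds
#' @return data.frame of interaction edges (one per residue pair).
#' @export
find_pipi <- function(s, p = interaction_params()) {
  pipi_core(prep_atoms(s), p)
}

#' Detect pi-cation interactions
#'
#' A cationic-group mass center (Arg guanidinium or Lys ammonium; His is not
#' counted as a cation here) at most `p$pication_cutoff` (default 5.0 A) from
#' an aromatic ring center of another residue.
#'
#' @inheritParams find_hbonds
#' @return data.frame of interaction edges.
#' @export
find_pication <- function(s, p = interaction_params()) {
  pication_core(prep_atoms(s), p)
}

# ---- network assembly -------------------------------------------------------

.detector_cores <- list(hbond = hbond_core, vdw = vdw_core,
                        ssbond = ssbond_core, ionic = ionic_core,
                        pipi = pipi_core, pication = pication_core)

#' Build the residue interaction network of one snapshot
#'
#' Runs the six interaction detectors, drops pairs of the same chain closer in
#' sequence than `p$min_seq_separation`, collapses parallel interactions into
#' a single undirected graph edge (full per-interaction detail is retained),
#' and keeps isolated residues as nodes. Nodes are residues, conceptually
#' placed at their alpha carbons; the graph is simple and unweighted.
#'
#' @inheritParams find_hbonds
#' @return An object of class `rin`: list with `graph` (igraph), `nodes`
#'   (residue keys), `edges` (one row per graph edge: `a`, `b`, comma-joined
#'   `types`, `min_distance`, `energy` of the closest interaction,
#'   `n_interactions`), and `detail` (every detected interaction).
#' @examples
#' spec <- toy_spec(n_residues = 3, backbone = "ring",
#'                  planted = list(list(pair = c(1, 2), itype = "hbond")))
#' g <- build_network(make_structure(spec))
#' g$edges
#' @export
build_network <- function(s, p = interaction_params()) {
  stopifnot(inherits(s, "Snapshot"))
  if (!nrow(s$atoms)) stop("empty snapshot: no atoms")
  at <- prep_atoms(s)
  detail <- do.call(rbind, lapply(.detector_cores, function(f) f(at, p)))
  rownames(detail) <- NULL
  # sequence-separation filter (same chain only); keys are CHAIN:zero-padded
  if (nrow(detail) && p$min_seq_separation > 1L) {
    cha <- substr(detail$a, 1, nchar(detail$a) - 7L)
    chb <- substr(detail$b, 1, nchar(detail$b) - 7L)
    ra <- as.integer(substr(detail$a, nchar(detail$a) - 5L, nchar(detail$a)))
    rb <- as.integer(substr(detail$b, nchar(detail$b) - 5L, nchar(detail$b)))
    keep <- cha != chb | abs(ra - rb) >= p$min_seq_separation
    detail <- detail[keep, , drop = FALSE]
  }
  nodes <- sort(unique(s$atoms$key))
  if (nrow(detail)) {
    pair <- paste(detail$a, detail$b, sep = "\r")
    ord <- order(pair, detail$distance)
    detail <- detail[ord, , drop = FALSE]
    pair <- pair[ord]
    first <- !duplicated(pair)
    types <- tapply(detail$itype, pair, function(x)
      paste(sort(unique(x)), collapse = ","))
    edges <- data.frame(
      a = detail$a[first], b = detail$b[first],
      types = as.character(types[pair[first]]),
      min_distance = detail$distance[first],
      energy = detail$energy[first],
      n_interactions = as.integer(table(pair)[pair[first]]),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(), types = character(),
                        min_distance = numeric(), energy = numeric(),
                        n_interactions = integer(), stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$a, nodes),
                                    match(edges$b, nodes)))
  }
  structure(list(graph = g, nodes = nodes, edges = edges, detail = detail,
                 params = p, model_index = s$model_index),
            class = "rin")
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf("Residue interaction network: %d nodes, %d edges (%d interactions)\n",
              length(x$nodes), nrow(x$edges), nrow(x$detail)))
  if (nrow(x$detail)) {
    print(table(x$detail$itype))
  }
  invisible(x)
}

#' Network (shortest-path) distance between two residues
#'
#' The number of edges in the shortest path linking two residue nodes in the
#' interaction network; 0 for identical nodes, `Inf` when disconnected.
#'
#' @param g a `rin` object (or igraph with residue-key vertex names).
#' @param a,b residue identifiers (`"A:98"` style accepted).
#' @return Integer path length or `Inf`.
#' @export
network_distance <- function(g, a, b) {
  graph <- if (inherits(g, "rin")) g$graph else g
  a <- as_residue_key(a); b <- as_residue_key(b)
  nm <- igraph::V(graph)$name
  if (!(a %in% nm) || !(b %in% nm)) {
    stop("unknown node: ", format_residue_key(setdiff(c(a, b), nm)[1]))
  }
  d <- igraph::distances(graph, v = a, to = b)[1, 1]
  if (is.finite(d)) as.integer(d) else Inf
}

#' Write a network edge list as TSV
#'
#' Columns: `chain_a`, `res_a`, `chain_b`, `res_b`, `types` (comma-joined),
#' `min_distance`, `energy`. A `# config:` header line records the detection
#' parameters.
#'
#' @param g a `rin` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "rin"))
  p <- g$params
  hdr <- sprintf(
    "# config: hbond=%g vdw=%g ssbond=%g ionic=%g pipi=%g pication=%g min_seq_separation=%d his_cationic=%s his_aromatic=%s",
    p$hbond_cutoff, p$vdw_surface_cutoff, p$ssbond_cutoff, p$ionic_cutoff,
    p$pipi_cutoff, p$pication_cutoff, p$min_seq_separation,
    p$his_cationic, p$his_aromatic)
  e <- g$edges
  sa <- strsplit(e$a, ":", fixed = TRUE)
  sb <- strsplit(e$b, ":", fixed = TRUE)
  out <- data.frame(
    chain_a = vapply(sa, `[`, "", 1),
    res_a = as.integer(vapply(sa, `[`, "", 2)),
    chain_b = vapply(sb, `[`, "", 1),
    res_b = as.integer(vapply(sb, `[`, "", 2)),
    types = e$types, min_distance = round(e$min_distance, 4),
    energy = e$energy, stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
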