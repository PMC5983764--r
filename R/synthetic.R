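# Synthetic structures and ensembles with known ground truth.
#
# These generators are chemically minimal on purpose: the interaction
# detectors read only distances and atom typing, so correctness testing needs
# controlled geometry, not stereochemically valid proteins. Planted
# interactions are realized with >= 0.2 A margin inside their cutoff;
# non-planted pairs are kept clear of their cutoffs where the backbone
# geometry allows it.

# distance targets used when planting each interaction type; all sit inside
# the default cutoff with a margin of at least 0.2 A
.plant_target <- c(hbond = 3.2, vdw = 3.65, ssbond = 2.2, ionic = 3.7,
                   pipi = 5.8, pication = 4.3)

#' Specification of a synthetic toy structure / ensemble
#'
#' @param n_residues number of residues (chain `"A"`, numbered from 1).
#' @param backbone CA placement rule: `"extended"` (straight line, 5 A
#'   spacing), `"helix"` (ideal alpha-helix CA trace: 2.3 A radius, 1.5 A
#'   rise, 100 degrees per residue), or `"ring"` (circle with 5 A chords).
#' @param planted list of planted interactions, each
#'   `list(pair = c(i, j), itype = "hbond")` with `itype` one of
#'   `hbond, vdw, ssbond, ionic, pipi, pication`.
#' @param jitter_sigma Gaussian coordinate noise (A) applied to ensemble
#'   snapshots; default 0.1, well below the 0.2 A planting margin.
#' @param event `list(triple = c(a, b, c), f = fraction)`: in a Bernoulli(f)
#'   subset of ensemble snapshots the three residues are closed into a
#'   mutual-contact (disulfide) triangle; otherwise the triangle is broken by
#'   displacing the third residue's contact atom.
#' @param backbone_polar give every residue backbone N and O atoms (useful for
#'   hydrogen-bond detector tests on helices).
#' @param seed RNG seed for ensemble generation (default 20180510).
#' @return A `toy_spec` object.
#' @export
toy_spec <- function(n_residues, backbone = c("extended", "helix", "ring"),
                     planted = list(), jitter_sigma = 0.1,
                     event = NULL, backbone_polar = FALSE, seed = 20180510) {
  backbone <- match.arg(backbone)
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 1L, jitter_sigma >= 0)
  for (pl in planted) {
    if (!all(pl$pair %in% seq_len(n_residues))) {
      stop("planted pair outside 1..n_residues")
    }
    if (!pl$itype %in% names(.plant_target)) stop("unknown itype: ", pl$itype)
  }
  if (!is.null(event)) {
    stopifnot(length(event$triple) == 3L,
              event$f >= 0, event$f <= 1)
    if (!all(event$triple %in% seq_len(n_residues))) {
      stop("event triple not in structure")
    }
  }
  structure(list(n_residues = n_residues, backbone = backbone,
                 planted = planted, jitter_sigma = jitter_sigma,
                 event = event, backbone_polar = isTRUE(backbone_polar),
                 seed = as.integer(seed)),
            class = "toy_spec")
}

backbone_ca <- function(spec) {
  n <- spec$n_residues
  i <- seq_len(n) - 1L
  switch(spec$backbone,
    extended = cbind(x = 5.0 * i, y = 0, z = 0),
    helix = {
      phi <- i * 100 * pi / 180
      cbind(x = 2.3 * cos(phi), y = 2.3 * sin(phi), z = 1.5 * i)
    },
    ring = {
      r <- 2.5 / sin(pi / max(n, 2L))
      phi <- 2 * pi * i / n
      cbind(x = r * cos(phi), y = r * sin(phi), z = 0)
    })
}

unit <- function(v) v / sqrt(sum(v^2))

# a unit vector perpendicular to u (used to lift aromatic rings off the
# backbone so ring atoms stay clear of CA contact range)
perp <- function(u) {
  w <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(w - sum(w * u) * u)
}

hexagon <- function(center, u, radius = 1.39) {
  # ring in the plane perpendicular to u
  e1 <- perp(u)
  e2 <- unit(pracma_cross(u, e1))
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a) center + radius * (cos(a) * e1 + sin(a) * e2),
           numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# internal builder: atoms of one snapshot from CA coordinates.
# event_closed switches the event triangle between closed and broken; the
# planted/event contact atoms are derived from the *current* CA positions so
# a planted interaction always meets its criterion even under jitter.
toy_atoms <- function(spec, ca, event_closed = TRUE) {
  n <- spec$n_residues
  res_name <- rep("GLY", n)
  want_res <- function(i, what) {
    if (res_name[i] != "GLY" && res_name[i] != what) {
      stop(sprintf("infeasible planting: residue %d needed as both %s and %s",
                   i, res_name[i], what))
    }
    res_name[i] <<- what
  }
  # plain vector accumulators: this runs once per ensemble snapshot
  a_resno <- integer(); a_name <- character(); a_ele <- character()
  a_xyz <- list()
  placed <- new.env(hash = TRUE, parent = emptyenv())
  add_atom <- function(i, name, element, xyz) {
    key <- paste(i, name)
    if (!is.null(placed[[key]])) {
      if (max(abs(placed[[key]] - xyz)) > 1e-9) {
        stop(sprintf("infeasible planting: atom %s of residue %d placed twice",
                     name, i))
      }
      return(invisible())
    }
    placed[[key]] <- xyz
    m <- length(a_resno) + 1L
    a_resno[m] <<- i; a_name[m] <<- name; a_ele[m] <<- element
    a_xyz[[m]] <<- xyz
  }
  for (i in seq_len(n)) add_atom(i, "CA", "C", ca[i, ])
  if (spec$backbone_polar) {
    for (i in seq_len(n)) {
      towards <- function(j) unit(ca[j, ] - ca[i, ])
      if (i > 1L) add_atom(i, "N", "N", ca[i, ] + 1.2 * towards(i - 1L))
      if (i < n) add_atom(i, "O", "O", ca[i, ] + 1.2 * towards(i + 1L))
    }
  }
  plant <- function(i, j, itype) {
    u <- unit(ca[j, ] - ca[i, ])
    D <- sqrt(sum((ca[j, ] - ca[i, ])^2))
    d <- .plant_target[[itype]]
    t <- (D - d) / 2
    if (itype == "hbond") {
      add_atom(i, "N", "N", ca[i, ] + t * u)
      add_atom(j, "O", "O", ca[j, ] - t * u)
    } else if (itype == "vdw") {
      add_atom(i, "CB", "C", ca[i, ] + t * u)
      add_atom(j, "CB", "C", ca[j, ] - t * u)
    } else if (itype == "ssbond") {
      want_res(i, "CYS"); want_res(j, "CYS")
      add_atom(i, "SG", "S", ca[i, ] + t * u)
      add_atom(j, "SG", "S", ca[j, ] - t * u)
    } else if (itype == "ionic") {
      want_res(i, "LYS"); want_res(j, "ASP")
      add_atom(i, "NZ", "N", ca[i, ] + t * u)
      center <- ca[j, ] - t * u
      # coincident carboxylate cluster keeps the group mass center exact
      add_atom(j, "CG", "C", center)
      add_atom(j, "OD1", "O", center)
      add_atom(j, "OD2", "O", center)
    } else if (itype == "pipi") {
      want_res(i, "PHE"); want_res(j, "PHE")
      w <- perp(u)
      ci <- ca[i, ] + t * u + 2.5 * w
      cj <- ca[j, ] - t * u + 2.5 * w
      ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      hi <- hexagon(ci, u); hj <- hexagon(cj, u)
      for (m in 1:6) add_atom(i, ring_names[m], "C", hi[m, ])
      for (m in 1:6) add_atom(j, ring_names[m], "C", hj[m, ])
    } else if (itype == "pication") {
      want_res(i, "LYS"); want_res(j, "PHE")
      w <- perp(u)
      cj <- ca[j, ] - 0.5 * u + 2.5 * w
      add_atom(i, "NZ", "N", cj - d * u)
      ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      hj <- hexagon(cj, u)
      for (m in 1:6) add_atom(j, ring_names[m], "C", hj[m, ])
    }
  }
  for (pl in spec$planted) plant(pl$pair[1], pl$pair[2], pl$itype)
  if (!is.null(spec$event)) {
    tr <- spec$event$triple
    for (i in tr) want_res(i, "CYS")
    centroid <- colMeans(ca[tr, , drop = FALSE])
    base <- centroid + c(0, 0, 5)
    side <- .plant_target[["ssbond"]]
    rad <- side / sqrt(3)
    ang <- c(0, 2 * pi / 3, 4 * pi / 3)
    for (m in 1:3) {
      pos <- base + rad * c(cos(ang[m]), sin(ang[m]), 0)
      if (!event_closed && m == 3L) pos <- pos + c(0, 0, 6)
      add_atom(tr[m], "SG", "S", pos)
    }
  }
  xyz <- do.call(rbind, a_xyz)
  ord <- order(a_resno, a_name != "CA", a_name)
  m <- length(ord)
  out <- list(
    eleno = seq_len(m), atom_name = a_name[ord], element = a_ele[ord],
    altloc = rep("", m), res_name = res_name[a_resno[ord]],
    chain = rep("A", m), seq_index = a_resno[ord],
    x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3],
    occupancy = rep(1, m), is_hydrogen = rep(FALSE, m),
    is_het = rep(FALSE, m), key = residue_key("A", a_resno[ord]))
  attr(out, "row.names") <- seq_len(m)
  class(out) <- "data.frame"
  out
}

#' Build a single toy structure
#'
#' Places CA atoms on the requested backbone, then adds the minimal atoms
#' needed to realize each planted interaction at a distance comfortably inside
#' its cutoff (>= 0.2 A margin). An event triple, when present, is realized in
#' its closed (triangle) state. After assembly the structure's network is
#' checked against the planted pairs; any extra, geometrically unavoidable
#' edges (e.g. CA-CA van der Waals contacts of a helix) are reported via a
#' message and the `"unplanned_edges"` attribute.
#'
#' @param spec a [toy_spec()].
#' @return A [Snapshot][read_structure].
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  ca <- backbone_ca(spec)
  s <- new_snapshot(toy_atoms(spec, ca, event_closed = TRUE), 1L)
  want <- unique(c(
    vapply(spec$planted, function(pl) {
      paste(sort(residue_key("A", pl$pair)), collapse = "|")
    }, ""),
    if (!is.null(spec$event)) {
      tr <- spec$event$triple
      apply(utils::combn(sort(residue_key("A", tr)), 2), 2,
            paste, collapse = "|")
    }))
  g <- build_network(s)
  got <- paste(g$edges$a, g$edges$b, sep = "|")
  extra <- setdiff(got, want)
  if (length(extra)) {
    message(length(extra), " unplanned edge(s) in synthetic structure (reported in attr)")
    attr(s, "unplanned_edges") <- extra
  }
  s
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Build a synthetic conformational ensemble with a controlled event rate
#'
#' Generates `N` snapshots of the toy structure. Each snapshot's CA positions
#' receive independent Gaussian jitter (`jitter_sigma`); planted-interaction
#' atoms and the event triple's contact atoms are re-derived from the
#' jittered CA positions, so every planted interaction meets its criterion in
#' every snapshot regardless of jitter. In a seeded Bernoulli(`f`) subset of
#' snapshots the event triple forms a closed mutual-contact triangle (so the
#' pair shares a 3-clique); in the rest one triangle contact is broken. The
#' realized per-snapshot event indicator is returned as the ground-truth
#' ledger in attribute `"events"`.
#'
#' @param spec a [toy_spec()] (its `event` and `seed` fields drive the
#'   Bernoulli draw).
#' @param N number of snapshots (>= 1).
#' @return An [Ensemble][read_structure] with attribute `events` (logical N).
#' @examples
#' spec <- toy_spec(3, "ring", event = list(triple = c(1, 2, 3), f = 0.5))
#' e <- make_ensemble(spec, 10)
#' mean(attr(e, "events"))
#' @export
make_ensemble <- function(spec, N) {
  stopifnot(inherits(spec, "toy_spec"), N >= 1)
  N <- as.integer(N)
  ca0 <- backbone_ca(spec)
  with_seed(spec$seed, {
    events <- if (is.null(spec$event)) rep(TRUE, N) else
      stats::runif(N) < spec$event$f
    snaps <- lapply(seq_len(N), function(i) {
      ca <- ca0 + matrix(stats::rnorm(length(ca0), 0, spec$jitter_sigma),
                         ncol = 3)
      new_snapshot(toy_atoms(spec, ca, event_closed = events[i]), i)
    })
    e <- new_ensemble(snaps)
    attr(e, "events") <- events
    e
  })
}

#' Random graph ensemble with a forced event triangle
#'
#' Bypasses geometry: generates `N` Erdos-Renyi graphs `G(n, p)` (vertex names
#' `"1" ... "n"`). Per graph, a seeded Bernoulli(`f`) draw decides whether the
#' event triangle is forced present (its three edges added) or broken (the
#' edge between the first and third triple member removed). Useful for
#' community-detection tests at the graph level.
#'
#' @param n_nodes number of vertices.
#' @param edge_prob edge probability in `[0, 1]`.
#' @param event `list(triple = c(a, b, c), f = fraction)` or `NULL`.
#' @param N number of graphs.
#' @param seed RNG seed.
#' @return List of igraph objects with attribute `events` (logical N).
#' @export
make_graph_ensemble <- function(n_nodes, edge_prob, event = NULL, N = 1L,
                                seed = 20180510) {
  stopifnot(edge_prob >= 0, edge_prob <= 1, N >= 1)
  with_seed(seed, {
    events <- if (is.null(event)) rep(TRUE, N) else
      stats::runif(N) < event$f
    graphs <- lapply(seq_len(N), function(i) {
      g <- igraph::sample_gnp(n_nodes, edge_prob)
      igraph::V(g)$name <- as.character(seq_len(n_nodes))
      if (!is.null(event)) {
        tr <- as.character(event$triple)
        if (events[i]) {
          for (m in list(tr[1:2], tr[2:3], tr[c(1, 3)])) {
            if (!igraph::are_adjacent(g, m[1], m[2])) {
              g <- igraph::add_edges(g, m)
            }
          }
        } else if (igraph::are_adjacent(g, tr[1], tr[3])) {
          g <- igraph::delete_edges(g, paste(tr[1], tr[3], sep = "|"))
        }
      }
      g
    })
    attr(graphs, "events") <- events
    graphs
  })
}

#' Random typed-atom snapshot for detector stress tests
#'
#' Scatters residues of assorted types (Gly, Cys, Met, Lys, Arg, Asp, Glu,
#' Ser, Phe, Tyr, His, Trp) in a cubic box, each with its CA plus the
#' side-chain atoms its type contributes to interaction detection, at random
#' small offsets from the CA. The resulting atom cloud produces many
#' near-cutoff distances of every interaction type, which makes it a good
#' input for comparing detectors against brute-force scans.
#'
#' @param n_residues number of residues.
#' @param box box edge length, A.
#' @param seed RNG seed.
#' @return A [Snapshot][read_structure].
#' @export
make_random_snapshot <- function(n_residues, box = 18, seed = 20180510) {
  sidechains <- list(
    GLY = NULL,
    CYS = list(c("SG", "S")),
    MET = list(c("SD", "S")),
    SER = list(c("OG", "O")),
    LYS = list(c("NZ", "N")),
    ASP = list(c("CG", "C"), c("OD1", "O"), c("OD2", "O")),
    GLU = list(c("CD", "C"), c("OE1", "O"), c("OE2", "O")),
    ARG = list(c("CZ", "C"), c("NE", "N"), c("NH1", "N"), c("NH2", "N")),
    HIS = list(c("CG", "C"), c("ND1", "N"), c("CD2", "C"), c("CE1", "C"),
               c("NE2", "N")),
    PHE = list(c("CG", "C"), c("CD1", "C"), c("CD2", "C"), c("CE1", "C"),
               c("CE2", "C"), c("CZ", "C")),
    TYR = list(c("CG", "C"), c("CD1", "C"), c("CD2", "C"), c("CE1", "C"),
               c("CE2", "C"), c("CZ", "C"), c("OH", "O")),
    TRP = list(c("CG", "C"), c("CD1", "C"), c("NE1", "N"), c("CE2", "C"),
               c("CD2", "C"), c("CZ2", "C"), c("CH2", "C"), c("CZ3", "C"),
               c("CE3", "C"))
  )
  with_seed(seed, {
    types <- sample(names(sidechains), n_residues, replace = TRUE)
    rows <- list()
    for (i in seq_len(n_residues)) {
      ca <- stats::runif(3, 0, box)
      rows[[length(rows) + 1L]] <- c(i, "CA", "C", ca)
      rows[[length(rows) + 1L]] <- c(i, "N", "N", ca + stats::rnorm(3, 0, 0.8))
      rows[[length(rows) + 1L]] <- c(i, "O", "O", ca + stats::rnorm(3, 0, 0.8))
      for (at in sidechains[[types[i]]]) {
        rows[[length(rows) + 1L]] <-
          c(i, at[1], at[2], ca + stats::rnorm(3, 0, 1.5))
      }
    }
    m <- do.call(rbind, rows)
    atoms <- data.frame(
      eleno = seq_len(nrow(m)), atom_name = m[, 2], element = m[, 3],
      altloc = "", res_name = types[as.integer(m[, 1])], chain = "A",
      seq_index = as.integer(m[, 1]),
      x = as.numeric(m[, 4]), y = as.numeric(m[, 5]), z = as.numeric(m[, 6]),
      occupancy = 1, is_hydrogen = FALSE, is_het = FALSE,
      key = residue_key("A", as.integer(m[, 1])), stringsAsFactors = FALSE)
    new_snapshot(atoms, 1L)
  })
}
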