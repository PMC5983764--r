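p0 <- interaction_params()

test_that("hydrogen bonds respect the donor-acceptor distance cutoff", {
  near <- two_atom_snap("GLY", "N", "N", "GLY", "O", "O", 3.4)
  far <- two_atom_snap("GLY", "N", "N", "GLY", "O", "O", 3.6)
  expect_equal(nrow(find_hbonds(near, p0)), 1)
  expect_equal(find_hbonds(near, p0)$itype, "hbond")
  expect_equal(nrow(find_hbonds(far, p0)), 0)
  # acceptor-only pairs are not bonds: two backbone O at close range
  oo <- two_atom_snap("GLY", "O", "O", "GLY", "O", "O", 3.0)
  expect_equal(nrow(find_hbonds(oo, p0)), 0)
})

test_that("hbond energies are tiered on distance", {
  d <- c(2.4, 2.9, 3.4)
  snaps <- lapply(d, function(x) two_atom_snap("GLY", "N", "N", "GLY", "O", "O", x))
  en <- vapply(snaps, function(s) find_hbonds(s, p0)$energy, 1)
  expect_equal(en, c(115.0, 40.0, 17.0))
})

test_that("van der Waals contact uses the surface (radius-subtracted) gap", {
  # two carbons r = 1.7: centers 3.8 apart -> gap 0.4 (edge); 4.0 -> 0.6 (none)
  near <- two_atom_snap("GLY", "CA", "C", "GLY", "CA", "C", 3.8)
  far <- two_atom_snap("GLY", "CA", "C", "GLY", "CA", "C", 4.0)
  expect_equal(nrow(find_vdw(near, p0)), 1)
  expect_equal(find_vdw(near, p0)$distance, 0.4, tolerance = 1e-9)
  expect_equal(nrow(find_vdw(far, p0)), 0)
})

test_that("disulfide detection is CYS-SG specific", {
  expect_equal(nrow(find_disulfide(
    two_atom_snap("CYS", "SG", "S", "CYS", "SG", "S", 2.0), p0)), 1)
  expect_equal(nrow(find_disulfide(
    two_atom_snap("CYS", "SG", "S", "CYS", "SG", "S", 2.6), p0)), 0)
  # MET sulfurs never count
  expect_equal(nrow(find_disulfide(
    two_atom_snap("MET", "SD", "S", "MET", "SD", "S", 2.0), p0)), 0)
})

test_that("ionic edges need opposite charges within the cutoff", {
  lys_asp <- make_snap(resno = c(1, 2, 2, 2),
                       res = c("LYS", "ASP", "ASP", "ASP"),
                       name = c("NZ", "CG", "OD1", "OD2"),
                       element = c("N", "C", "O", "O"),
                       x = c(0, 3.5, 3.5, 3.5), y = 0 * 1:4, z = 0 * 1:4)
  expect_equal(nrow(find_ionic(lys_asp, p0)), 1)
  # same sign: Lys-Arg at close range is never ionic
  lys_arg <- two_atom_snap("LYS", "NZ", "N", "ARG", "CZ", "C", 3.5)
  expect_equal(nrow(find_ionic(lys_arg, p0)), 0)
  # the distance is between group mass centers, not closest atoms
  far <- make_snap(resno = c(1, 2, 2, 2),
                   res = c("LYS", "ASP", "ASP", "ASP"),
                   name = c("NZ", "CG", "OD1", "OD2"),
                   element = c("N", "C", "O", "O"),
                   x = c(0, 4.1, 4.1, 4.1), y = 0 * 1:4, z = 0 * 1:4)
  expect_equal(nrow(find_ionic(far, p0)), 0)
})

test_that("pi-pi stacking uses ring geometric centers and skips broken rings", {
  ring_at <- function(resno, cx) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    list(resno = rep(resno, 6),
         res = rep("PHE", 6),
         name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
         element = rep("C", 6),
         x = rep(cx, 6), y = 1.39 * cos(ang), z = 1.39 * sin(ang))
  }
  r1 <- ring_at(1, 0); r2 <- ring_at(2, 5.0)
  s <- make_snap(c(r1$resno, r2$resno), c(r1$res, r2$res),
                 c(r1$name, r2$name), c(r1$element, r2$element),
                 c(r1$x, r2$x), c(r1$y, r2$y), c(r1$z, r2$z))
  e <- find_pipi(s, p0)
  expect_equal(nrow(e), 1)
  expect_equal(e$distance, 5.0, tolerance = 1e-9)
  # centers 6.6 apart: no edge
  r3 <- ring_at(2, 6.6)
  s2 <- make_snap(c(r1$resno, r3$resno), c(r1$res, r3$res),
                  c(r1$name, r3$name), c(r1$element, r3$element),
                  c(r1$x, r3$x), c(r1$y, r3$y), c(r1$z, r3$z))
  expect_equal(nrow(find_pipi(s2, p0)), 0)
  # drop one ring atom -> incomplete ring skipped with a warning
  s3 <- make_snap(c(r1$resno[-1], r2$resno), c(r1$res[-1], r2$res),
                  c(r1$name[-1], r2$name), c(r1$element[-1], r2$element),
                  c(r1$x[-1], r2$x), c(r1$y[-1], r2$y), c(r1$z[-1], r2$z))
  expect_warning(e3 <- find_pipi(s3, p0), "incomplete")
  expect_equal(nrow(e3), 0)
})

test_that("pi-cation pairs a cationic center with a ring center", {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  mk <- function(d) make_snap(
    resno = c(1, rep(2, 6)), res = c("LYS", rep("PHE", 6)),
    name = c("NZ", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    element = c("N", rep("C", 6)),
    x = c(0, rep(d, 6)), y = c(0, 1.39 * cos(ang)), z = c(0, 1.39 * sin(ang)))
  expect_equal(nrow(find_pication(mk(4.0), p0)), 1)
  expect_equal(nrow(find_pication(mk(5.1), p0)), 0)
})

test_that("every detector matches its naive all-pairs oracle on random clouds", {
  for (seed in c(11, 23, 57)) {
    s <- make_random_snapshot(45, box = 16, seed = seed)
    expect_identical(edge_pairs(find_hbonds(s, p0)), oracle_hbond_pairs(s))
    expect_identical(edge_pairs(find_vdw(s, p0)), oracle_vdw_pairs(s))
    expect_identical(edge_pairs(find_disulfide(s, p0)), oracle_ssbond_pairs(s))
    expect_identical(edge_pairs(find_ionic(s, p0)), oracle_ionic_pairs(s))
    expect_identical(edge_pairs(find_pipi(s, p0)), oracle_pipi_pairs(s))
    expect_identical(edge_pairs(find_pication(s, p0)), oracle_pication_pairs(s))
  }
})

test_that("build_network unions the detectors and collapses parallel edges", {
  spec <- toy_spec(3, "extended",
                   planted = list(list(pair = c(1, 2), itype = "hbond")))
  g <- build_network(make_structure(spec))
  # donor-acceptor atoms within 3.5 A are also within vdW surface range, so
  # the single planted pair carries two interactions on one graph edge
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$types, "hbond,vdw")
  expect_equal(g$edges$n_interactions, 2)
  expect_length(g$nodes, 3)        # isolated node 3 kept
  # compositional check on a random cloud: network edge set equals the union
  # of the six detectors run independently
  s <- make_random_snapshot(30, box = 14, seed = 8)
  g2 <- build_network(s, p0)
  union_pairs <- sort(unique(c(
    edge_pairs(find_hbonds(s, p0)), edge_pairs(find_vdw(s, p0)),
    edge_pairs(find_disulfide(s, p0)), edge_pairs(find_ionic(s, p0)),
    edge_pairs(find_pipi(s, p0)), edge_pairs(find_pication(s, p0)))))
  expect_identical(edge_pairs(g2$edges), union_pairs)
  expect_error(build_network(make_snap(integer(), character(), character(),
                                       character(), numeric(), numeric(),
                                       numeric())),
               "empty")
})

test_that("min_seq_separation filters sequence-local pairs of one chain", {
  s <- two_atom_snap("GLY", "N", "N", "GLY", "O", "O", 3.0)
  expect_equal(nrow(build_network(s, p0)$edges), 1)
  p3 <- interaction_params(min_seq_separation = 3)
  expect_equal(nrow(build_network(s, p3)$edges), 0)
})

test_that("every reported edge satisfies its own distance criterion when re-measured", {
  s <- make_random_snapshot(40, box = 15, seed = 31)
  g <- build_network(s, p0)
  cuts <- c(hbond = p0$hbond_cutoff, vdw = p0$vdw_surface_cutoff,
            ssbond = p0$ssbond_cutoff, ionic = p0$ionic_cutoff,
            pipi = p0$pipi_cutoff, pication = p0$pication_cutoff)
  expect_true(all(g$detail$distance <= cuts[g$detail$itype] + 1e-12))
})

test_that("edges are invariant under rigid rotation and residue reordering", {
  s <- make_random_snapshot(35, box = 15, seed = 12)
  g1 <- edge_pairs(build_network(s, p0)$edges)
  # rotate about z by 35 degrees and translate
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 10; s2$atoms$y <- xyz[, 2] - 4; s2$atoms$z <- xyz[, 3]
  expect_identical(edge_pairs(build_network(s2, p0)$edges), g1)
  # shuffle atom row order
  s3 <- s
  set.seed(1)
  s3$atoms <- s3$atoms[sample(nrow(s3$atoms)), ]
  expect_identical(edge_pairs(build_network(s3, p0)$edges), g1)
})

test_that("raising a cutoff never removes an edge of that type", {
  s <- make_random_snapshot(35, box = 15, seed = 44)
  base <- edge_pairs(find_hbonds(s, p0))
  wider <- edge_pairs(find_hbonds(s, interaction_params(hbond_cutoff = 4.2)))
  expect_true(all(base %in% wider))
  basev <- edge_pairs(find_vdw(s, p0))
  widerv <- edge_pairs(find_vdw(s, interaction_params(vdw_surface_cutoff = 1.0)))
  expect_true(all(basev %in% widerv))
})

test_that("the network is simple and undirected: degree sums to 2|E|", {
  s <- make_random_snapshot(30, box = 14, seed = 3)
  g <- build_network(s, p0)
  expect_false(igraph::any_multiple(g$graph))
  expect_equal(sum(igraph::degree(g$graph)), 2 * nrow(g$edges))
})

test_that("network_distance equals a BFS oracle and handles edge cases", {
  s <- make_random_snapshot(25, box = 14, seed = 19)
  g <- build_network(s, p0)
  expect_equal(network_distance(g, "A:1", "A:1"), 0)
  if (nrow(g$edges)) {
    e1 <- g$edges[1, ]
    expect_equal(network_distance(g, e1$a, e1$b), 1)
  }
  set.seed(77)
  pick <- replicate(12, sample(g$nodes, 2), simplify = FALSE)
  for (pr in pick) {
    expect_equal(network_distance(g, pr[1], pr[2]),
                 bfs_distance(g$graph, pr[1], pr[2]))
  }
  expect_error(network_distance(g, "A:1", "Z:999"), "unknown node")
})

test_that("edge list TSV round-trips through the writer", {
  spec <- toy_spec(4, "ring",
                   planted = list(list(pair = c(1, 3), itype = "ssbond")))
  g <- build_network(make_structure(spec))
  tf <- tempfile(fileext = ".tsv")
  write_edge_list(g, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "^# config:")
  tab <- utils::read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), nrow(g$edges))
  expect_true(all(c("chain_a", "res_a", "types", "min_distance") %in% names(tab)))
})
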