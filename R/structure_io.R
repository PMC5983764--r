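#' Residue node identifiers
#'
#' A residue is identified by its chain and author (PDB) residue number. The
#' key is a plain character string that is stable under re-parsing, usable as
#' a name/hash, and order-comparable: sorting keys sorts by chain, then by
#' residue number (`"A:98"` sorts before `"A:152"` because the number is
#' zero-padded internally).
#'
#' @param chain chain identifier (single character, typically).
#' @param seq_index author residue number (integer).
#' @return Character vector of residue keys.
#' @examples
#' residue_key("A", 98)
#' sort(residue_key("A", c(152, 98)))
#' @export
residue_key <- function(chain, seq_index) {
  seq_index <- as.integer(seq_index)
  if (any(is.na(seq_index))) stop("seq_index must be integer")
  if (any(is.na(chain) | !nzchar(chain))) stop("chain must be non-empty")
  sprintf("%s:%06d", chain, seq_index)
}

#' Normalise a user-supplied residue identifier
#'
#' Accepts `"A:98"` (any padding) or an already-normalised key and returns the
#' canonical zero-padded key used throughout the package.
#'
#' @param x character vector like `"A:98"`.
#' @return Canonical residue keys.
#' @export
as_residue_key <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("residue identifiers must look like CHAIN:RESNUM, got: ",
                     x[which(bad)[1]])
  residue_key(vapply(parts, `[`, "", 1L),
              as.integer(vapply(parts, `[`, "", 2L)))
}

#' Pretty form of a residue key
#' @param key canonical residue key.
#' @return `"A:98"`-style labels.
#' @export
format_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  sprintf("%s:%d", vapply(parts, `[`, "", 1L),
          as.integer(vapply(parts, `[`, "", 2L)))
}

# the three-letter codes treated as amino acids; everything else is HET
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

new_snapshot <- function(atoms, model_index = 1L) {
  stopifnot(is.data.frame(atoms))
  structure(list(model_index = as.integer(model_index), atoms = atoms),
            class = "Snapshot")
}

new_ensemble <- function(snapshots) {
  structure(snapshots, class = "Ensemble")
}

#' @export
print.Snapshot <- function(x, ...) {
  cat(sprintf("Snapshot (model %d): %d residues, %d atoms\n",
              x$model_index, length(unique(x$atoms$key)), nrow(x$atoms)))
  invisible(x)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d snapshots (%d residues each)\n",
              length(x),
              if (length(x)) length(unique(x[[1]]$atoms$key)) else 0L))
  invisible(x)
}

#' @export
length.Ensemble <- function(x) {
  length(unclass(x))
}

#' Residue table of a snapshot
#'
#' @param s a `Snapshot`.
#' @return data.frame with one row per residue: `key`, `chain`, `seq_index`,
#'   `res_name`, `has_ca` (complete residues carry an alpha carbon).
#' @export
snapshot_residues <- function(s) {
  stopifnot(inherits(s, "Snapshot"))
  a <- s$atoms
  keep <- !duplicated(a$key)
  out <- data.frame(key = a$key[keep], chain = a$chain[keep],
                    seq_index = a$seq_index[keep],
                    res_name = a$res_name[keep],
                    stringsAsFactors = FALSE)
  has_ca <- tapply(a$atom_name == "CA", a$key, any)
  out$has_ca <- as.logical(has_ca[out$key])
  rownames(out) <- NULL
  out
}

# altloc resolution: keep, per (residue, atom name), the record with highest
# occupancy; ties go to altloc 'A' (then first in file order).
resolve_altloc <- function(atoms) {
  alt <- atoms$altloc
  if (all(is.na(alt) | alt == "")) return(atoms)
  id <- paste(atoms$key, atoms$atom_name, sep = "\r")
  pref <- ifelse(is.na(alt) | alt == "", 0L, ifelse(alt == "A", 1L, 2L))
  ord <- order(id, -atoms$occupancy, pref, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$key, atoms$atom_name, sep = "\r")), ,
                 drop = FALSE]
  atoms[order(atoms$chain, atoms$seq_index, atoms$eleno), , drop = FALSE]
}

# build the per-model atom data.frame from a bio3d atom table + xyz row
atoms_from_bio3d <- function(at, xyz, keep_het) {
  n <- nrow(at)
  idx <- seq_len(n)
  coords <- matrix(xyz, ncol = 3, byrow = TRUE)
  ele <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1, 1), at$elesy)))
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- data.frame(
    eleno = at$eleno,
    atom_name = trimws(at$elety),
    element = ele,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    res_name = trimws(at$resid),
    chain = chain,
    seq_index = as.integer(at$resno),
    x = coords[idx, 1], y = coords[idx, 2], z = coords[idx, 3],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_hydrogen = ele %in% c("H", "D"),
    is_het = at$type != "ATOM" | !(trimws(at$resid) %in% .aa3),
    stringsAsFactors = FALSE
  )
  if (keep_het) atoms$is_het <- FALSE
  atoms <- atoms[!atoms$is_het, , drop = FALSE]
  atoms$key <- residue_key(atoms$chain, atoms$seq_index)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in structure")
  }
  atoms <- resolve_altloc(atoms)
  rownames(atoms) <- NULL
  atoms
}

#' Read a structure or conformational ensemble from a PDB file
#'
#' Parses a (possibly multi-model) PDB file into the package's coordinate
#' model. Each MODEL record becomes one [Snapshot]; a file without MODEL
#' records is a single implicit model. Alternate locations are resolved to the
#' highest-occupancy record (ties broken in favour of altloc `'A'`).
#' Hydrogens are retained but flagged (`is_hydrogen`); interaction detection
#' uses heavy atoms only. Waters, ions and other heteroatoms are dropped by
#' default, so the network is over amino acids.
#'
#' @param path PDB file path.
#' @param model integer model number, or `"all"` to read the full ensemble.
#' @param keep_het keep heteroatom records (default drops them).
#' @return A `Snapshot` if a single model is requested or the file has one
#'   model; an `Ensemble` for `model = "all"` with several models.
#' @examples
#' pdb <- system.file("extdata", "toy_ensemble_synthetic.pdb",
#'                    package = "rinpab")
#' e <- read_structure(pdb, model = "all")
#' length(e)
#' @export
read_structure <- function(path, model = "all", keep_het = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  snaps <- lapply(seq_len(nmod), function(i) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[i, ] else pdb$xyz
    s <- new_snapshot(atoms_from_bio3d(pdb$atom, xyz, keep_het), i)
    res <- snapshot_residues(s)
    if (any(!res$has_ca)) {
      warning(sprintf("model %d: %d residue(s) without CA flagged incomplete (%s)",
                      i, sum(!res$has_ca),
                      paste(format_residue_key(res$key[!res$has_ca]),
                            collapse = ", ")),
              call. = FALSE)
    }
    s
  })
  keysets <- lapply(snaps, function(s) sort(unique(s$atoms$key)))
  if (length(snaps) > 1L &&
      !all(vapply(keysets[-1], identical, TRUE, keysets[[1]]))) {
    stop("inconsistent residue sets across models")
  }
  if (identical(model, "all")) {
    if (nmod == 1L) return(snaps[[1]])
    return(new_ensemble(snaps))
  }
  model <- as.integer(model)
  if (is.na(model) || model < 1L || model > nmod) {
    stop(sprintf("requested model %s but file has %d model(s)", model, nmod))
  }
  snaps[[model]]
}

#' Coerce to an Ensemble
#'
#' Extension point for trajectory sources other than multi-model PDB: any
#' list of `Snapshot` objects (e.g. produced by a custom reader) can be used
#' wherever an ensemble is expected.
#'
#' @param x a `Snapshot`, a list of `Snapshot`s, or an `Ensemble`.
#' @return An `Ensemble`.
#' @export
as_ensemble <- function(x) {
  if (inherits(x, "Ensemble")) return(x)
  if (inherits(x, "Snapshot")) return(new_ensemble(list(x)))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "Snapshot"))) {
    return(new_ensemble(x))
  }
  stop("cannot coerce to Ensemble")
}

#' Write snapshots to a (multi-model) PDB file
#'
#' @param x a `Snapshot` or `Ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  snaps <- if (inherits(x, "Snapshot")) list(x) else as_ensemble(x)
  a <- snaps[[1]]$atoms
  xyz <- do.call(rbind, lapply(snaps, function(s) {
    as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)),
                   eleno = seq_len(nrow(a)),
                   elety = a$atom_name, resid = a$res_name,
                   chain = a$chain, resno = a$seq_index,
                   o = a$occupancy, b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}
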