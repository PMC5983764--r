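#' Interaction detection parameters
#'
#' Distance cutoffs, per-type energy annotations and atom typing options used
#' to detect the six non-covalent interaction types of a residue interaction
#' network. Defaults are the standard cutoffs used for residue-interaction
#' network generation: hydrogen bond 3.5 A (heavy donor to heavy acceptor),
#' van der Waals surface gap 0.5 A, disulfide S-S 2.5 A, ionic (group mass
#' centers) 4.0 A, pi-pi ring centers 6.5 A, pi-cation 5.0 A.
#'
#' Energies are reporting annotations only (kJ/mol, averaged per interaction
#' class); no downstream graph algorithm uses them. Hydrogen-bond energies are
#' tiered on donor-acceptor distance: <= 2.5 A -> 115.0, <= 3.0 A -> 40.0,
#' otherwise 17.0.
#'
#' @param hbond_cutoff hydrogen-bond donor-acceptor heavy-atom distance, A.
#' @param vdw_surface_cutoff van der Waals surface-to-surface gap, A.
#' @param ssbond_cutoff disulfide SG-SG distance, A.
#' @param ionic_cutoff distance between oppositely charged group mass
#'   centers, A.
#' @param pipi_cutoff aromatic ring geometric-center distance, A.
#' @param pication_cutoff cationic-group mass center to ring center
#'   distance, A.
#' @param energies named list of per-type annotation energies (kJ/mol);
#'   `hbond` is a length-3 vector for the distance tiers.
#' @param vdw_radii named vector of van der Waals radii per element symbol, A
#'   (Bondi values for the elements found in amino acids).
#' @param min_seq_separation minimum |sequence index difference| for an edge
#'   between residues of the same chain; the default 1 excludes only
#'   self-pairs so that sequence-adjacent contacts are kept.
#' @param his_cationic treat histidine's imidazole as a positively charged
#'   group for ionic interactions.
#' @param his_aromatic treat histidine's imidazole as an aromatic ring for
#'   pi-pi stacking.
#'
#' @return An object of class `interaction_params` (a validated list).
#' @examples
#' p <- interaction_params()
#' p$hbond_cutoff
#' interaction_params(hbond_cutoff = 3.2)$hbond_cutoff
#' @export
interaction_params <- function(hbond_cutoff = 3.5,
                               vdw_surface_cutoff = 0.5,
                               ssbond_cutoff = 2.5,
                               ionic_cutoff = 4.0,
                               pipi_cutoff = 6.5,
                               pication_cutoff = 5.0,
                               energies = list(
                                 hbond = c(115.0, 40.0, 17.0),
                                 vdw = 6.0,
                                 ssbond = 167.0,
                                 ionic = 20.0,
                                 pipi = 9.4,
                                 pication = 9.6
                               ),
                               vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                             S = 1.80),
                               min_seq_separation = 1L,
                               his_cationic = TRUE,
                               his_aromatic = TRUE) {
  p <- list(
    hbond_cutoff = hbond_cutoff,
    vdw_surface_cutoff = vdw_surface_cutoff,
    ssbond_cutoff = ssbond_cutoff,
    ionic_cutoff = ionic_cutoff,
    pipi_cutoff = pipi_cutoff,
    pication_cutoff = pication_cutoff,
    energies = energies,
    vdw_radii = vdw_radii,
    min_seq_separation = as.integer(min_seq_separation),
    his_cationic = isTRUE(his_cationic),
    his_aromatic = isTRUE(his_aromatic)
  )
  cuts <- c(p$hbond_cutoff, p$vdw_surface_cutoff, p$ssbond_cutoff,
            p$ionic_cutoff, p$pipi_cutoff, p$pication_cutoff)
  if (!all(is.finite(cuts)) || any(cuts <= 0)) {
    stop("all interaction cutoffs must be positive and finite")
  }
  if (is.na(p$min_seq_separation) || p$min_seq_separation < 1L) {
    stop("min_seq_separation must be an integer >= 1")
  }
  if (is.null(names(p$vdw_radii)) || any(p$vdw_radii <= 0)) {
    stop("vdw_radii must be a named vector of positive radii")
  }
  class(p) <- "interaction_params"
  p
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Interaction parameters (distances in Angstrom):\n")
  cat(sprintf("  hbond <= %.2f | vdw gap <= %.2f | ssbond <= %.2f\n",
              x$hbond_cutoff, x$vdw_surface_cutoff, x$ssbond_cutoff))
  cat(sprintf("  ionic <= %.2f | pipi <= %.2f | pication <= %.2f\n",
              x$ionic_cutoff, x$pipi_cutoff, x$pication_cutoff))
  cat(sprintf("  min_seq_separation = %d; His cationic: %s, aromatic: %s\n",
              x$min_seq_separation, x$his_cationic, x$his_aromatic))
  invisible(x)
}

# hbond energy annotation tier by donor-acceptor distance (A)
hbond_energy <- function(d, energies) {
  tiers <- energies$hbond
  ifelse(d <= 2.5, tiers[1], ifelse(d <= 3.0, tiers[2], tiers[3]))
}

#' Read interaction parameters from a config file
#'
#' Accepts either JSON (an object whose fields are `interaction_params()`
#' arguments) or simple `key = value` lines. Unknown keys are an error.
#'
#' @param path config file path.
#' @return An `interaction_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  if (startsWith(first, "{")) {
    vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                               simplifyVector = TRUE)
  } else {
    txt <- txt[!grepl("^\\s*(#|$)", txt)]
    kv <- strsplit(txt, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed config line: ", txt[which(bad)[1]])
    vals <- lapply(kv, function(x) {
      v <- trimws(x[2])
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
    })
    names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  }
  known <- names(formals(interaction_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(interaction_params, vals)
}
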