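#' Thermodynamic additivity statistics for double mutations
#'
#' For a double-site mutation with single-mutant free-energy changes
#' `ddg_i`, `ddg_j` and double-mutant change `ddg_ij`, the additive
#' expectation is `ddg_sum = ddg_i + ddg_j` and the additivity deviation is
#' `dddg = ddg_ij - ddg_sum`. A perfectly additive pair has `dddg = 0`; the
#' larger `|dddg|`, the stronger the coupling between the two sites. Rows
#' missing any of the three components (the usual situation when one of the
#' single mutants was never measured) are dropped with a message; the drop
#' count is attached as attribute `n_dropped`. Units (kJ/mol or kcal/mol) are
#' whatever the input table uses and are carried through unchanged.
#'
#' @param records data.frame with numeric columns `ddg_i`, `ddg_j`, `ddg_ij`
#'   (any other columns are preserved).
#' @return The table with complete rows only, plus columns `ddg_sum` and
#'   `dddg`; attribute `n_dropped` gives the number of dropped rows.
#' @examples
#' compute_additivity(data.frame(ddg_i = 1, ddg_j = 2, ddg_ij = 3))
#' @export
compute_additivity <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("ddg_i", "ddg_j", "ddg_ij")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cn in need) {
    v <- records[[cn]]
    if (is.character(v) || is.factor(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- !is.na(v) & v != "" & is.na(v2)
      if (any(bad)) {
        stop(sprintf("non-numeric value in column %s, row %d: '%s'",
                     cn, which(bad)[1], as.character(v)[which(bad)[1]]))
      }
      records[[cn]] <- v2
    }
  }
  complete <- stats::complete.cases(records[, need])
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(sprintf("dropped %d record(s) lacking a single- or double-mutant measurement",
                    n_dropped))
  }
  out <- records[complete, , drop = FALSE]
  out$ddg_sum <- out$ddg_i + out$ddg_j
  out$dddg <- out$ddg_ij - out$ddg_sum
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Alpha-carbon distance between two residues
#'
#' Euclidean distance (A) between the CA atoms of two residues in one
#' snapshot — the "virtual edge" length used to relate mutation coupling to
#' site separation.
#'
#' @param s a [Snapshot][read_structure].
#' @param a,b residue identifiers (`"A:98"` style).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(s, a, b) {
  stopifnot(inherits(s, "Snapshot"))
  a <- as_residue_key(a); b <- as_residue_key(b)
  at <- s$atoms
  ca <- function(k) {
    i <- which(at$key == k & at$atom_name == "CA")
    if (!length(i)) stop("no CA atom for residue ", format_residue_key(k))
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  sqrt(sum((ca(a) - ca(b))^2))
}

#' Correlate observed and predicted additivity deviations
#'
#' Pearson product-moment correlation between observed and predicted
#' delta-delta-delta-G values, with the Spearman rank correlation reported
#' alongside as a robustness check.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3, all
#'   finite, non-constant).
#' @return List with `pearson`, `spearman`, `n`.
#' @examples
#' compare_predictions(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
compare_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < 3L) stop("need at least 3 value pairs")
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("all values must be finite")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance: correlation undefined")
  }
  list(pearson = stats::cor(observed, predicted),
       spearman = stats::cor(observed, predicted, method = "spearman"),
       n = length(observed))
}

#' Read a double-mutation thermodynamics table
#'
#' CSV with at least `ddg_i`, `ddg_j`, `ddg_ij`; conventional optional columns
#' are `label_i`, `label_j`, `label_ij` (mutation strings such as "A98V"),
#' `site_i`, `site_j` (residue numbers) and `units`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
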