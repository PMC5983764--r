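#' Classify a clique co-membership probability as additive or non-additive
#'
#' A double-site mutation is predicted non-additive when the probability that
#' its two sites share a 3-clique community across the conformational ensemble
#' is at least the threshold (default 0.1, boundary inclusive).
#'
#' @param p_ab numeric vector of probabilities in `[0, 1]`.
#' @param threshold classification threshold (default 0.1).
#' @return Character vector, `"non_additive"` or `"additive"`.
#' @examples
#' classify_additivity(c(0.48, 0.07, 0.10))
#' @export
classify_additivity <- function(p_ab, threshold = 0.1) {
  if (any(!is.finite(p_ab)) || any(p_ab < 0) || any(p_ab > 1)) {
    stop("p_ab must lie in [0, 1]")
  }
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  ifelse(p_ab >= threshold, "non_additive", "additive")
}

# indicator for one snapshot's community set (or triangle list)
pair_indicator <- function(cset, a, b, same_triangle = FALSE, triangles = NULL) {
  if (same_triangle) {
    for (tr in triangles) if ((a %in% tr) && (b %in% tr)) return(1L)
    return(0L)
  }
  same_community(cset, a, b)
}

# per-snapshot communities for a whole ensemble, computed once and reused
ensemble_communities <- function(e, p, k, same_triangle = FALSE,
                                 stride = 1L) {
  e <- as_ensemble(e)
  if (!length(e)) stop("empty ensemble")
  idx <- seq(1L, length(e), by = as.integer(stride))
  lapply(idx, function(i) {
    g <- build_network(e[[i]], p)
    if (same_triangle) {
      list(model = i, nodes = g$nodes, triangles = enumerate_k_cliques(g, k))
    } else {
      list(model = i, nodes = g$nodes, cset = clique_percolation(g, k))
    }
  })
}

pab_from_communities <- function(comms, a, b, threshold, k, same_triangle) {
  events <- vapply(comms, function(cc) {
    if (!(a %in% cc$nodes) || !(b %in% cc$nodes)) {
      stop(sprintf("pair (%s, %s) absent from snapshot model %d",
                   format_residue_key(a), format_residue_key(b), cc$model))
    }
    if (same_triangle) {
      pair_indicator(NULL, a, b, TRUE, cc$triangles)
    } else {
      pair_indicator(cc$cset, a, b)
    }
  }, 1L)
  n <- length(events)
  ne <- sum(events)
  p_ab <- ne / n
  data.frame(
    a = format_residue_key(a), b = format_residue_key(b),
    p_ab = p_ab, n_events = ne, n = n,
    se = sqrt(p_ab * (1 - p_ab) / n),
    classification = classify_additivity(p_ab, threshold),
    threshold = threshold, k = k, stringsAsFactors = FALSE
  )
}

#' Ensemble clique co-membership probability P_ab for one site pair
#'
#' For each snapshot of a conformational ensemble, builds the residue
#' interaction network, finds its k-clique communities, and evaluates the
#' indicator C_ab (1 when sites a and b share a community). P_ab is the mean
#' of the indicator over the ensemble: the fraction of snapshots in which the
#' two mutation sites are held in the same 3-clique structure. The pair is
#' classified non-additive when P_ab >= `threshold`.
#'
#' @param e an [Ensemble][read_structure] (or anything [as_ensemble()]
#'   accepts).
#' @param pair length-2 character vector of residue identifiers
#'   (`"A:98"`-style).
#' @param p [interaction_params()].
#' @param k clique size (default 3).
#' @param threshold classification threshold on P_ab (default 0.1).
#' @param same_triangle if `TRUE`, require a and b to lie in one and the same
#'   k-clique (single triangle) instead of the same percolation community.
#' @param stride evaluate every `stride`-th snapshot (default 1 = all).
#' @return One-row data.frame of class `pab_result`: `a`, `b`, `p_ab`,
#'   `n_events`, `n`, `se` (binomial standard error), `classification`,
#'   `threshold`, `k`.
#' @examples
#' spec <- toy_spec(n_residues = 3, backbone = "ring",
#'                  event = list(triple = c(1, 2, 3), f = 1))
#' e <- make_ensemble(spec, 20)
#' compute_pab(e, c("A:1", "A:2"))$p_ab
#' @export
compute_pab <- function(e, pair, p = interaction_params(), k = 3L,
                        threshold = 0.1, same_triangle = FALSE, stride = 1L) {
  stopifnot(length(pair) == 2L)
  a <- as_residue_key(pair[1])
  b <- as_residue_key(pair[2])
  comms <- ensemble_communities(e, p, k, same_triangle, stride)
  out <- pab_from_communities(comms, a, b, threshold, k, same_triangle)
  class(out) <- c("pab_result", class(out))
  out
}

#' P_ab table for several site pairs
#'
#' Networks and clique communities are computed once per snapshot and reused
#' across all pairs.
#'
#' @inheritParams compute_pab
#' @param pairs list of length-2 character vectors (or a 2-column matrix).
#' @return data.frame of class `pab_table`, one row per pair, with the columns
#'   of [compute_pab()].
#' @export
pab_table <- function(e, pairs, p = interaction_params(), k = 3L,
                      threshold = 0.1, same_triangle = FALSE, stride = 1L) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  if (!length(pairs)) {
    out <- data.frame(a = character(), b = character(), p_ab = numeric(),
                      n_events = integer(), n = integer(), se = numeric(),
                      classification = character(), threshold = numeric(),
                      k = integer(), stringsAsFactors = FALSE)
    class(out) <- c("pab_table", class(out))
    return(out)
  }
  comms <- ensemble_communities(e, p, k, same_triangle, stride)
  rows <- lapply(pairs, function(pr) {
    pab_from_communities(comms, as_residue_key(pr[1]), as_residue_key(pr[2]),
                         threshold, k, same_triangle)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pab_table", class(out))
  out
}

#' @export
print.pab_table <- function(x, digits = 3, ...) {
  cat(sprintf("P_ab over %s snapshots (k = %s, threshold = %s):\n",
              paste(unique(x$n), collapse = "/"),
              paste(unique(x$k), collapse = "/"),
              paste(unique(x$threshold), collapse = "/")))
  y <- as.data.frame(x)
  y$p_ab <- round(y$p_ab, digits)
  y$se <- signif(y$se, 3)
  print(y[, c("a", "b", "p_ab", "n_events", "n", "se", "classification")],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.pab_result <- function(x, ...) {
  cat(sprintf("P_%s,%s = %.4g (%d/%d snapshots, se %.3g) -> %s (threshold %g, k = %d)\n",
              x$a, x$b, x$p_ab, x$n_events, x$n, x$se, x$classification,
              x$threshold, x$k))
  invisible(x)
}

#' Write a P_ab table to JSON or TSV
#'
#' @param x a `pab_table` or `pab_result`.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pab <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  y <- as.data.frame(x)
  if (format == "json") {
    jsonlite::write_json(y, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
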