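#' Range-normalize a score vector onto [lo, hi]
#'
#' Affine map of `[min(x), max(x)]` onto `[lo, hi]`.  A constant vector
#' maps every entry to `lo`, so that a multiplicative combination of
#' normalized components never annihilates a node.
#'
#' @param x numeric vector (names preserved).
#' @param lo,hi target range endpoints, `lo < hi`.  Defaults 1 and 100.
#' @return Numeric vector of the same length and names.
#' @export
range_normalize <- function(x, lo = 1, hi = 100) {
  if (!length(x)) stop("cannot normalize an empty vector", call. = FALSE)
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  x <- as.numeric(x)
  rng <- range(x)
  out <- if (rng[1L] == rng[2L]) {
    rep.int(lo, length(x))
  } else {
    lo + (x - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo)
  }
  names(out) <- names(x)
  out
}

# normalized component columns shared by spreading and hubness
.norm_components <- function(ct) {
  list(
    dc = range_normalize(ct$dc),
    bc = range_normalize(ct$bc),
    nc = range_normalize(ct$nc),
    lh = range_normalize(ct$lh),
    cr = range_normalize(ct$cr),
    ci = range_normalize(ct$ci)
  )
}

#' Spreading score
#'
#' Measures a node's capacity to disseminate influence through the
#' network.  Each component centrality is first range-normalized to
#' \[1,100\] (primed); then
#' `spreading_raw = (nc' + cr') * (bc' + ci')`, combining the semi-local
#' terms (neighborhood connectivity, ClusterRank) with the global ones
#' (betweenness, collective influence).  The raw product is
#' range-normalized again for reporting.
#'
#' @param ct centrality table from [all_centralities()].
#' @return data.frame with `node`, `spreading_raw`, `spreading`.
#' @export
spreading_score <- function(ct) {
  comp <- .norm_components(ct)
  raw <- (comp$nc + comp$cr) * (comp$bc + comp$ci)
  data.frame(
    node = ct$node,
    spreading_raw = as.numeric(raw),
    spreading = as.numeric(range_normalize(raw)),
    stringsAsFactors = FALSE
  )
}

#' Hubness score
#'
#' Measures a node's dominance over its immediate surroundings:
#' `hubness_raw = dc' + lh'`, the sum of the range-normalized degree and
#' local H-index, normalized again for reporting.
#'
#' @param ct centrality table from [all_centralities()].
#' @return data.frame with `node`, `hubness_raw`, `hubness`.
#' @export
hubness_score <- function(ct) {
  comp <- .norm_components(ct)
  raw <- comp$dc + comp$lh
  data.frame(
    node = ct$node,
    hubness_raw = as.numeric(raw),
    hubness = as.numeric(range_normalize(raw)),
    stringsAsFactors = FALSE
  )
}

#' Integrated Value of Influence (IVI)
#'
#' The package's node-prioritization statistic: the product of the
#' normalized hubness and spreading scores, range-normalized to \[1,100\].
#' On any graph with non-constant raw scores the top node therefore
#' scores exactly 100 and the bottom node exactly 1.
#'
#' @param ct centrality table from [all_centralities()].
#' @return data.frame (one row per node) with columns `node`,
#'   `spreading_raw`, `hubness_raw`, `ivi_raw`, `spreading`, `hubness`,
#'   `ivi`.
#' @export
ivi <- function(ct) {
  sp <- spreading_score(ct)
  hb <- hubness_score(ct)
  ivi_raw <- hb$hubness * sp$spreading
  data.frame(
    node = ct$node,
    spreading_raw = sp$spreading_raw,
    hubness_raw = hb$hubness_raw,
    ivi_raw = as.numeric(ivi_raw),
    spreading = sp$spreading,
    hubness = hb$hubness,
    ivi = as.numeric(range_normalize(ivi_raw)),
    stringsAsFactors = FALSE
  )
}

#' Top-k nodes by an influence column
#'
#' @param tbl influence table from [ivi()].
#' @param k number of rows to return (truncated to the table size).
#' @param by ranking column: `"ivi"`, `"spreading"` or `"hubness"`.
#' @return data.frame with `rank`, `node`, `score`, sorted descending;
#'   ties broken lexicographically by node symbol.
#' @export
rank_top <- function(tbl, k = 20L, by = c("ivi", "spreading", "hubness")) {
  by <- match.arg(by)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ord <- order(-tbl[[by]], tbl$node)
  k <- min(as.integer(k), nrow(tbl))
  idx <- ord[seq_len(k)]
  data.frame(
    rank = seq_len(k),
    node = tbl$node[idx],
    score = tbl[[by]][idx],
    stringsAsFactors = FALSE
  )
}

#' Write an influence score table
#'
#' Tab-separated with 5-decimal reals, nodes sorted lexicographically.
#'
#' @param tbl influence table from [ivi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_influence_table <- function(tbl, path) {
  out <- tbl[order(tbl$node), ]
  for (cn in setdiff(names(out), "node")) {
    out[[cn]] <- sprintf("%.5f", out[[cn]])
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
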