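#' Undirected simple gene networks
#'
#' `gene_network` is the package's graph container: an undirected simple
#' graph over uppercase gene symbols.  Self-loops and duplicate (or
#' reversed-duplicate) edges are removed at construction; nodes are kept in
#' lexicographic order so that every downstream table and serialization is
#' deterministic.  Edge weights, if supplied by a file, are parsed and
#' stored but ignored by all algorithms: the analyses here are purely
#' topological.
#'
#' @param from,to character vectors of endpoint symbols (recycled pairwise).
#' @param nodes optional character vector of additional node symbols to
#'   retain (e.g. isolated nodes).
#' @return An object of class `gene_network` with components:
#'   \describe{
#'     \item{nodes}{character vector, lexicographically sorted.}
#'     \item{edges}{two-column integer matrix of node indices, `i < j`,
#'       rows sorted.}
#'     \item{adj}{adjacency list: for each node, the sorted integer indices
#'       of its neighbours.}
#'     \item{dropped}{counts of self-loops and duplicate records removed.}
#'   }
#' @examples
#' net <- gene_network(c("A", "B", "B"), c("B", "C", "A"))
#' network_summary(net)
#' @export
gene_network <- function(from, to, nodes = NULL) {
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length", call. = FALSE)
  }
  keep <- nzchar(from) & nzchar(to)
  from <- from[keep]
  to <- to[keep]
  self <- from == to
  n_self <- sum(self)
  # nodes seen only in self-loops are retained as isolated nodes
  all_syms <- sort(unique(c(from, to, toupper(trimws(as.character(nodes))))))
  all_syms <- all_syms[nzchar(all_syms)]
  from <- from[!self]
  to <- to[!self]
  i <- match(from, all_syms)
  j <- match(to, all_syms)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]
  hi <- hi[!dup]
  ord <- order(lo, hi)
  edges <- cbind(lo[ord], hi[ord])
  storage.mode(edges) <- "integer"
  structure(
    list(
      nodes = all_syms,
      edges = edges,
      adj = .build_adj(length(all_syms), edges),
      dropped = c(self_loops = n_self, duplicates = n_dup)
    ),
    class = "gene_network"
  )
}

.build_adj <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(edges)) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    for (nm in names(nb)) adj[[as.integer(nm)]] <- sort(unname(nb[[nm]]))
  }
  adj
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d nodes, %d edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Node symbols of a network
#' @param net a `gene_network`.
#' @return Character vector of node symbols, lexicographically sorted.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$nodes
}

#' Node degrees
#' @param net a `gene_network`.
#' @return Named integer vector of degrees, in node order.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- vapply(net$adj, length, integer(1))
  names(d) <- net$nodes
  d
}

#' Edge list as a character data frame
#' @param net a `gene_network`.
#' @return data.frame with columns `from`, `to` (from < to, rows sorted).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  data.frame(
    from = net$nodes[net$edges[, 1L]],
    to = net$nodes[net$edges[, 2L]],
    stringsAsFactors = FALSE
  )
}

#' Read a gene network from a file
#'
#' Supported formats: two- or three-column tab-separated edge list (third
#' column taken as a weight and ignored by all algorithms), SIF
#' (`node1<TAB>relation<TAB>node2 [node3 ...]`, fanned out to one edge per
#' trailing node), and GraphML.  Self-loops are dropped, duplicate and
#' reversed-duplicate edges collapsed; the counts of dropped records are
#' stored in the `dropped` field of the result.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return A [gene_network].
#' @export
read_network <- function(path, format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    net <- gene_network(el[, 1L], el[, 2L],
      nodes = igraph::vertex_attr(g, "name")
    )
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty network file: ", path, call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (format == "edgelist") {
      bad <- which(vapply(parts, length, integer(1)) < 2L)
      if (length(bad)) {
        stop("malformed edge-list line ", bad[1L], " in ", path,
          call. = FALSE
        )
      }
      from <- vapply(parts, `[[`, character(1), 1L)
      to <- vapply(parts, `[[`, character(1), 2L)
      net <- gene_network(from, to)
    } else { # sif
      bad <- which(vapply(parts, length, integer(1)) < 3L)
      if (length(bad)) {
        stop("malformed SIF line ", bad[1L], " in ", path, call. = FALSE)
      }
      from <- character(0)
      to <- character(0)
      for (p in parts) {
        tgt <- p[3:length(p)]
        from <- c(from, rep(p[1L], length(tgt)))
        to <- c(to, tgt)
      }
      net <- gene_network(from, to)
    }
  }
  if (!length(net$nodes)) stop("empty graph in ", path, call. = FALSE)
  net
}

#' Write a gene network to a file
#'
#' Writers emit sorted, deterministic output: edges with `from < to`, rows
#' in lexicographic order.
#'
#' @param net a [gene_network].
#' @param path output file path.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("edgelist", "sif", "graphml")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  el <- network_edges(net)
  if (format == "edgelist") {
    utils::write.table(el, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  } else if (format == "sif") {
    isolated <- setdiff(net$nodes, unique(c(el$from, el$to)))
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(el)) {
      writeLines(paste(el$from, "interacts", el$to, sep = "\t"), con)
    }
    if (length(isolated)) writeLines(isolated, con)
  } else {
    g <- .as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# igraph is used only for GraphML serialization and as an independent
# oracle in the test-suite; all algorithms run on the native adjacency list.
.as_igraph <- function(net) {
  igraph::graph_from_data_frame(network_edges(net),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Summarize a network
#' @param net a [gene_network].
#' @return List with `nodes`, `edges`, `density`, `degree_min`,
#'   `degree_median`, `degree_max`, `components`.  Density is
#'   `2|E| / (|V|(|V|-1))` for two or more nodes, 0 otherwise.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  m <- nrow(net$edges)
  d <- network_degrees(net)
  list(
    nodes = n,
    edges = m,
    density = if (n >= 2L) 2 * m / (n * (n - 1)) else 0,
    degree_min = if (n) min(d) else NA_integer_,
    degree_median = if (n) stats::median(d) else NA_real_,
    degree_max = if (n) max(d) else NA_integer_,
    components = .n_components(net)
  )
}

.n_components <- function(net) {
  n <- length(net$nodes)
  if (!n) {
    return(0L)
  }
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in net$adj[[v]]) {
        if (!comp[w]) {
          comp[w] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  k
}

#' Induced subgraph
#'
#' Keeps exactly the edges with both endpoints in `nodes`.
#'
#' @param net a [gene_network].
#' @param nodes character vector of node symbols, all present in `net`.
#' @return A [gene_network] on `nodes`.
#' @export
induced_subgraph <- function(net, nodes) {
  stopifnot(inherits(net, "gene_network"))
  nodes <- toupper(trimws(as.character(nodes)))
  unknown <- setdiff(nodes, net$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(nodes, net$nodes)
  keep <- net$edges[, 1L] %in% idx & net$edges[, 2L] %in% idx
  e <- net$edges[keep, , drop = FALSE]
  gene_network(net$nodes[e[, 1L]], net$nodes[e[, 2L]], nodes = nodes)
}
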