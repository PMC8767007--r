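# shared graph constructors and independent oracles

path_net <- function(n, labels = LETTERS[seq_len(n)]) {
  gene_network(labels[-n], labels[-1L])
}

cycle_net <- function(n, labels = LETTERS[seq_len(n)]) {
  gene_network(labels, labels[c(seq_len(n)[-1L], 1L)])
}

star_net <- function(n_leaves) {
  gene_network(rep("HUB", n_leaves), sprintf("L%02d", seq_len(n_leaves)))
}

complete_net <- function(n, labels = LETTERS[seq_len(n)]) {
  pairs <- utils::combn(n, 2L)
  gene_network(labels[pairs[1L, ]], labels[pairs[2L, ]])
}

# Erdos-Renyi gnp graph; isolated nodes retained
gnp_net <- function(n, p, labels = sprintf("V%03d", seq_len(n))) {
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  gene_network(labels[pairs[1L, keep]], labels[pairs[2L, keep]],
    nodes = labels
  )
}

gnp_connected <- function(n, p) {
  repeat {
    net <- gnp_net(n, p)
    if (network_summary(net)$components == 1L) {
      return(net)
    }
  }
}

net_to_igraph <- function(net) {
  igraph::graph_from_data_frame(network_edges(net),
    directed = FALSE,
    vertices = data.frame(name = network_nodes(net))
  )
}

# independent betweenness oracle: Floyd-Warshall distances plus explicit
# recursive enumeration of every geodesic (no shared code with the
# Brandes implementation under test)
oracle_betweenness_enum <- function(net) {
  n <- length(network_nodes(net))
  adj <- net$adj
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(net$edges)) {
    d[net$edges] <- 1
    d[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      upd <- nd < d[i, ]
      d[i, upd] <- nd[upd]
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      if (!is.finite(d[s, t]) || d[s, t] < 2) next
      paths <- list()
      grow <- function(path) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1L]] <<- path
          return()
        }
        for (w in adj[[v]]) {
          if ((length(path) - 1L) + 1L + d[w, t] == d[s, t]) {
            grow(c(path, w))
          }
        }
      }
      grow(s)
      sigma <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / sigma
      }
    }
  }
  names(bc) <- network_nodes(net)
  bc
}

# every labeled graph on n nodes (edge subsets of K_n); n <= 5 in practice
all_labeled_graphs <- function(n) {
  labels <- LETTERS[seq_len(n)]
  pairs <- utils::combn(n, 2L)
  m <- ncol(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L
    gene_network(labels[pairs[1L, keep]], labels[pairs[2L, keep]],
      nodes = labels
    )
  })
}

# relabel the nodes of a network through a named map
relabel_net <- function(net, map) {
  el <- network_edges(net)
  gene_network(unname(map[el$from]), unname(map[el$to]),
    nodes = unname(map[network_nodes(net)])
  )
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

extdata <- function(...) {
  system.file("extdata", ..., package = "ivinet", mustWork = TRUE)
}
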