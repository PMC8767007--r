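#' Scoring configuration for component centralities
#'
#' @param ci_radius hop distance `d` for collective influence; nodes at
#'   *exactly* this distance contribute (frontier convention).  Default 3,
#'   the convention of the influence-analysis literature.
#' @param clusterrank_base base of the clustering penalty `f(c) = base^-c`
#'   in ClusterRank.  Default 10, from the method's source literature.
#' @param lh_mode how the local H-index aggregates: `"closed_sum"` (default)
#'   is `lh(i) = h(i) + sum of h(j) over neighbours j`, propagating
#'   second-order information; `"second_order"` instead computes an H-index
#'   over the H-indices of the neighbourhood.
#' @return A list of class `score_config`.
#' @export
score_config <- function(ci_radius = 3L, clusterrank_base = 10,
                         lh_mode = c("closed_sum", "second_order")) {
  ci_radius <- as.integer(ci_radius)
  if (is.na(ci_radius) || ci_radius < 1L) {
    stop("ci_radius must be >= 1", call. = FALSE)
  }
  if (!is.numeric(clusterrank_base) || clusterrank_base <= 0) {
    stop("clusterrank_base must be positive", call. = FALSE)
  }
  structure(
    list(
      ci_radius = ci_radius,
      clusterrank_base = clusterrank_base,
      lh_mode = match.arg(lh_mode)
    ),
    class = "score_config"
  )
}

#' Degree centrality
#'
#' `dc(i) = sum over j != i of A_ij`: the number of neighbours.
#'
#' @param net a [gene_network].
#' @return Named integer vector, one entry per node in lexicographic order.
#' @export
degree_centrality <- function(net) {
  network_degrees(net)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness: for each unordered node pair
#' \{s, t\}, every interior node v of their geodesics receives
#' `sigma_st(v) / sigma_st`, where `sigma_st` counts shortest s-t paths.
#' Endpoints are excluded and disconnected pairs contribute nothing.
#' Computed with Brandes' dependency-accumulation algorithm (one BFS per
#' source; ordered-pair sums halved for the undirected graph).
#'
#' @param net a [gene_network].
#' @return Named numeric vector in node order.
#' @export
betweenness_centrality <- function(net) {
  n <- length(net$nodes)
  adj <- net$adj
  bc <- numeric(n)
  if (n < 3L) {
    names(bc) <- net$nodes
    return(bc)
  }
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    qh <- 1L
    qt <- 1L
    stack <- integer(n)
    sp <- 0L
    while (qh <= qt) {
      v <- queue[qh]
      qh <- qh + 1L
      sp <- sp + 1L
      stack[sp] <- v
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          qt <- qt + 1L
          queue[qt] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (idx in seq.int(sp, 1L)) {
      w <- stack[idx]
      pw <- preds[[w]]
      if (length(pw)) {
        coeff <- (1 + delta[w]) / sigma[w]
        delta[pw] <- delta[pw] + sigma[pw] * coeff
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2
  names(bc) <- net$nodes
  bc
}

#' Neighborhood connectivity
#'
#' Mean degree of a node's neighbours; 0 for isolated nodes.
#'
#' @param net a [gene_network].
#' @return Named numeric vector in node order.
#' @export
neighborhood_connectivity <- function(net) {
  d <- as.numeric(network_degrees(net))
  nc <- vapply(net$adj, function(nb) {
    if (!length(nb)) 0 else mean(d[nb])
  }, numeric(1))
  names(nc) <- net$nodes
  nc
}

# largest h with at least h values >= h
.h_of <- function(values) {
  if (!length(values)) {
    return(0L)
  }
  v <- sort(as.numeric(values), decreasing = TRUE)
  h <- 0L
  for (k in seq_along(v)) {
    if (v[k] >= k) h <- k else break
  }
  as.integer(h)
}

#' H-index centrality
#'
#' The greatest `h` such that the node has at least `h` neighbours of
#' degree at least `h`.  Isolated nodes score 0.
#'
#' @param net a [gene_network].
#' @return Named integer vector in node order.
#' @export
h_index <- function(net) {
  d <- network_degrees(net)
  h <- vapply(net$adj, function(nb) .h_of(d[nb]), integer(1))
  names(h) <- net$nodes
  h
}

#' Local H-index centrality
#'
#' Extends the H-index over the closed neighbourhood.  Under the default
#' `"closed_sum"` mode, `lh(i) = h(i) + sum of h(j) over neighbours j`,
#' which propagates second-order degree information.  The alternative
#' `"second_order"` mode computes an H-index over the neighbours'
#' H-indices instead (see [score_config]).
#'
#' @param net a [gene_network].
#' @param cfg a [score_config].
#' @return Named numeric vector in node order.
#' @export
local_h_index <- function(net, cfg = score_config()) {
  h <- h_index(net)
  lh <- if (cfg$lh_mode == "closed_sum") {
    vapply(seq_along(net$adj), function(i) {
      h[i] + sum(h[net$adj[[i]]])
    }, numeric(1))
  } else {
    vapply(seq_along(net$adj), function(i) {
      as.numeric(.h_of(h[net$adj[[i]]]))
    }, numeric(1))
  }
  names(lh) <- net$nodes
  lh
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected.
#' Nodes of degree < 2 score 0 (standard convention, avoids 0/0).
#'
#' @param net a [gene_network].
#' @return Named numeric vector in node order.
#' @export
clustering_coefficient <- function(net) {
  adj <- net$adj
  cc <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2L) {
      return(0)
    }
    links <- 0L
    for (u in nb) {
      # count neighbour pairs once: u < w
      links <- links + sum(adj[[u]] %in% nb[nb > u])
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  names(cc) <- net$nodes
  cc
}

#' ClusterRank
#'
#' `cr(i) = f(c_i) * sum over neighbours j of (dc(j) + 1)`, where `c_i` is
#' the local clustering coefficient of `i` and `f(c) = base^-c` penalizes
#' tightly clustered surroundings (default base 10).
#'
#' @param net a [gene_network].
#' @param cfg a [score_config].
#' @return Named numeric vector in node order.
#' @export
clusterrank <- function(net, cfg = score_config()) {
  d <- as.numeric(network_degrees(net))
  cc <- clustering_coefficient(net)
  cr <- vapply(seq_along(net$adj), function(i) {
    nb <- net$adj[[i]]
    if (!length(nb)) {
      return(0)
    }
    cfg$clusterrank_base^(-cc[i]) * sum(d[nb] + 1)
  }, numeric(1))
  names(cr) <- net$nodes
  cr
}

#' Collective influence
#'
#' `ci(i) = (dc(i) - 1) * sum over j at distance exactly d of (dc(j) - 1)`.
#' The frontier convention is used: only nodes at hop distance exactly
#' `d` (default 3) contribute; a node with no vertex at that distance
#' scores 0.  Distances are within connected components.
#'
#' @param net a [gene_network].
#' @param cfg a [score_config].
#' @return Named numeric vector in node order.
#' @export
collective_influence <- function(net, cfg = score_config()) {
  n <- length(net$nodes)
  adj <- net$adj
  d <- as.numeric(network_degrees(net))
  radius <- cfg$ci_radius
  ci <- numeric(n)
  for (s in seq_len(n)) {
    if (d[s] <= 1) next # reduced degree factor is 0
    dist <- rep.int(-1L, n)
    dist[s] <- 0L
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < radius) {
      depth <- depth + 1L
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    if (length(frontier)) {
      ci[s] <- (d[s] - 1) * sum(d[frontier] - 1)
    }
  }
  names(ci) <- net$nodes
  ci
}

#' All component centralities in one table
#'
#' Computes the seven per-node vectors used by the influence scores:
#' degree (`dc`), betweenness (`bc`), neighborhood connectivity (`nc`),
#' H-index (`h`), local H-index (`lh`), ClusterRank (`cr`) and collective
#' influence (`ci`).
#'
#' @param net a [gene_network].
#' @param cfg a [score_config].
#' @return data.frame with one row per node (lexicographic order),
#'   columns `node`, `dc`, `bc`, `nc`, `h`, `lh`, `cr`, `ci`.
#' @export
all_centralities <- function(net, cfg = score_config()) {
  data.frame(
    node = net$nodes,
    dc = as.integer(degree_centrality(net)),
    bc = as.numeric(betweenness_centrality(net)),
    nc = as.numeric(neighborhood_connectivity(net)),
    h = as.integer(h_index(net)),
    lh = as.numeric(local_h_index(net, cfg)),
    cr = as.numeric(clusterrank(net, cfg)),
    ci = as.numeric(collective_influence(net, cfg)),
    stringsAsFactors = FALSE
  )
}

#' Write a centrality table
#'
#' Tab-separated, one row per node sorted lexicographically, reals fixed
#' to six decimals.
#'
#' @param ct data.frame from [all_centralities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(ct, path) {
  out <- data.frame(
    node = ct$node,
    dc = ct$dc,
    bc = sprintf("%.6f", ct$bc),
    nc = sprintf("%.6f", ct$nc),
    h = ct$h,
    lh = sprintf("%.6f", ct$lh),
    cr = sprintf("%.6f", ct$cr),
    ci = sprintf("%.6f", ct$ci),
    stringsAsFactors = FALSE
  )
  utils::write.table(out[order(out$node), ], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
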