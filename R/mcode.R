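#' MCODE parameters
#'
#' The four numeric parameters follow the common tool defaults: degree
#' cutoff 2, node score cutoff 0.2, k-core 2, maximum traversal depth
#' 100.  Haircut is on and fluff off by default.
#'
#' @param degree_cutoff minimum degree for a node to receive a non-zero
#'   vertex weight.
#' @param node_score_cutoff fraction in \[0, 1): neighbours are included
#'   in a complex when their weight exceeds
#'   `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core complexes whose induced subgraph has no `k_core`-core
#'   are discarded in post-processing (>= 2).
#' @param max_depth breadth-first traversal depth from the seed node.
#' @param haircut iteratively remove complex members of induced degree
#'   < 2 during post-processing.
#' @param fluff add boundary neighbours whose closed-neighbourhood
#'   density exceeds `fluff_density` (fluffed nodes may repeat across
#'   complexes).
#' @param fluff_density density threshold for fluff.
#' @return List of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.1) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    stop("node_score_cutoff must lie in [0, 1)", call. = FALSE)
  }
  if (k_core < 2L) stop("k_core must be >= 2", call. = FALSE)
  structure(
    list(
      degree_cutoff = as.integer(degree_cutoff),
      node_score_cutoff = node_score_cutoff,
      k_core = as.integer(k_core),
      max_depth = as.integer(max_depth),
      haircut = isTRUE(haircut),
      fluff = isTRUE(fluff),
      fluff_density = fluff_density
    ),
    class = "mcode_params"
  )
}

#' k-core numbers
#'
#' Core number of each node by iterative minimum-degree peeling: the
#' largest k such that the node survives in the maximal subgraph of
#' minimum degree k.
#'
#' @param net a [gene_network].
#' @return Named integer vector in node order.
#' @export
core_numbers <- function(net) {
  n <- length(net$nodes)
  deg <- vapply(net$adj, length, integer(1))
  core <- integer(n)
  alive <- rep.int(TRUE, n)
  remaining <- n
  k <- 0L
  while (remaining > 0L) {
    repeat {
      peel <- which(alive & deg <= k)
      if (!length(peel)) break
      core[peel] <- k
      alive[peel] <- FALSE
      remaining <- remaining - length(peel)
      for (v in peel) {
        nb <- net$adj[[v]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  names(core) <- net$nodes
  core
}

# density of the highest k-core of `net`; returns c(kmax, density)
.max_core_density <- function(net) {
  core <- core_numbers(net)
  kmax <- max(core, 0L)
  if (kmax < 1L) {
    return(c(0, 0))
  }
  members <- net$nodes[core >= kmax]
  sub <- induced_subgraph(net, members)
  n <- length(sub$nodes)
  dens <- if (n >= 2L) 2 * nrow(sub$edges) / (n * (n - 1)) else 0
  c(kmax, dens)
}

#' MCODE vertex weights
#'
#' For each node v the closed neighbourhood graph G\[N(v) + v\] is
#' examined: the weight is `k_max * density(highest k-core)` of that
#' local graph.  Nodes whose neighbourhood has no 2-core, or whose
#' degree falls below `degree_cutoff`, weigh 0 — this is what stops
#' complex traversal at sparse bridges.
#'
#' @param net a [gene_network].
#' @param params an [mcode_params] list.
#' @return Named numeric vector in node order.
#' @export
vertex_weights <- function(net, params = mcode_params()) {
  n <- length(net$nodes)
  deg <- vapply(net$adj, length, integer(1))
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < params$degree_cutoff) next
    nhood <- net$nodes[c(v, net$adj[[v]])]
    local <- induced_subgraph(net, nhood)
    kd <- .max_core_density(local)
    if (kd[1L] >= 2) w[v] <- kd[1L] * kd[2L]
  }
  names(w) <- net$nodes
  w
}

.new_module <- function(net, members) {
  members <- sort(members)
  sub <- induced_subgraph(net, members)
  nn <- length(members)
  ne <- nrow(sub$edges)
  dens <- if (nn >= 2L) 2 * ne / (nn * (nn - 1)) else 0
  structure(
    list(
      members = members,
      node_count = nn,
      edge_count = ne,
      density = dens,
      mcode_score = dens * nn,
      seed_genes = character(0),
      he = NA_real_
    ),
    class = "mcode_module"
  )
}

#' @export
print.mcode_module <- function(x, ...) {
  cat(sprintf(
    "<mcode_module> %d nodes, %d edges, score %.3f\n",
    x$node_count, x$edge_count, x$mcode_score
  ))
  invisible(x)
}

#' MCODE complex prediction
#'
#' Stage two of the algorithm: repeatedly take the highest-weight
#' unassigned node with positive weight as a seed (ties broken
#' lexicographically by symbol for determinism) and grow a complex
#' breadth-first over unassigned neighbours whose weight exceeds
#' `seed_weight * (1 - node_score_cutoff)`, to at most `max_depth` hops.
#' Each node joins at most one complex.  Complexes are ordered by
#' MCODE score (`density * node_count`) descending, ties by first member
#' symbol.
#'
#' @param net a [gene_network].
#' @param weights named numeric vector from [vertex_weights()].
#' @param params an [mcode_params] list.
#' @return List of `mcode_module` objects.
#' @export
predict_complexes <- function(net, weights, params = mcode_params()) {
  n <- length(net$nodes)
  stopifnot(length(weights) == n)
  assigned <- rep.int(FALSE, n)
  complexes <- list()
  node_order <- order(-weights, net$nodes)
  for (seed in node_order) {
    if (assigned[seed] || weights[seed] <= 0) next
    threshold <- weights[seed] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      depth <- depth + 1L
      nxt <- integer(0)
      for (v in frontier) {
        for (u in net$adj[[v]]) {
          if (!assigned[u] && weights[u] > threshold) {
            assigned[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    complexes[[length(complexes) + 1L]] <-
      .new_module(net, net$nodes[members])
  }
  .order_modules(complexes)
}

.order_modules <- function(modules) {
  if (!length(modules)) {
    return(modules)
  }
  score <- vapply(modules, function(m) m$mcode_score, numeric(1))
  first <- vapply(modules, function(m) m$members[1L], character(1))
  modules[order(-score, first)]
}

#' MCODE post-processing
#'
#' Stage three: complexes whose induced subgraph lacks a `k_core`-core
#' are discarded; with haircut, members of induced degree < 2 are removed
#' iteratively; with fluff, boundary neighbours whose
#' closed-neighbourhood density exceeds `fluff_density` are added
#' (fluffed nodes may repeat across complexes).  Counts, density and
#' score are recomputed.
#'
#' @param complexes list of `mcode_module` from [predict_complexes()].
#' @param net the parent [gene_network].
#' @param params an [mcode_params] list.
#' @return Filtered, recomputed list of `mcode_module`.
#' @export
postprocess <- function(complexes, net, params = mcode_params()) {
  out <- list()
  for (m in complexes) {
    members <- m$members
    sub <- induced_subgraph(net, members)
    if (max(core_numbers(sub), 0L) < params$k_core) next
    if (params$haircut) {
      repeat {
        deg <- vapply(sub$adj, length, integer(1))
        drop <- sub$nodes[deg < 2L]
        if (!length(drop)) break
        members <- setdiff(members, drop)
        if (length(members) < 2L) break
        sub <- induced_subgraph(net, members)
      }
      if (length(members) < 2L) next
    }
    if (params$fluff) {
      idx <- match(members, net$nodes)
      boundary <- setdiff(
        net$nodes[unique(unlist(net$adj[idx]))], members
      )
      add <- character(0)
      for (b in boundary) {
        bi <- match(b, net$nodes)
        nhood <- net$nodes[c(bi, net$adj[[bi]])]
        local <- induced_subgraph(net, nhood)
        nn <- length(local$nodes)
        dens <- if (nn >= 2L) {
          2 * nrow(local$edges) / (nn * (nn - 1))
        } else {
          0
        }
        if (dens > params$fluff_density) add <- c(add, b)
      }
      members <- sort(unique(c(members, add)))
    }
    out[[length(out) + 1L]] <- .new_module(net, members)
  }
  .order_modules(out)
}

#' Detect dense modules in one call
#'
#' Convenience wrapper: [vertex_weights()], [predict_complexes()],
#' [postprocess()], then drops modules with fewer than `min_size` nodes
#' (reporting threshold; the smallest meaningful module is the
#' 3-node/3-edge motif).
#'
#' @param net a [gene_network].
#' @param params an [mcode_params] list.
#' @param min_size smallest module size kept (default 3).
#' @return List of `mcode_module`, ordered by MCODE score.
#' @export
find_modules <- function(net, params = mcode_params(), min_size = 3L) {
  w <- vertex_weights(net, params)
  mods <- postprocess(predict_complexes(net, w, params), net, params)
  Filter(function(m) m$node_count >= min_size, mods)
}

#' Recursive modular decomposition to motif level
#'
#' Applies module detection to the network, then recurses into each
#' module's induced subgraph, until modules are motifs (3 nodes, 3
#' edges) or decompose into nothing strictly smaller (a clique, for
#' instance, reproduces itself and becomes a leaf).
#'
#' @param net a [gene_network].
#' @param params an [mcode_params] list.
#' @return A `module_hierarchy`: list with `node_count`, `edge_count`
#'   (root graph) and `children`, a list of entries
#'   `list(module = <mcode_module>, level = <int>, children = ...)`.
#' @export
decompose_hierarchy <- function(net, params = mcode_params()) {
  recurse <- function(subnet, level) {
    mods <- find_modules(subnet, params)
    if (level > 1L) {
      # inside a module, only strictly smaller sub-modules count;
      # a module that reproduces itself (e.g. a clique) is a leaf
      mods <- Filter(
        function(m) m$node_count < length(subnet$nodes), mods
      )
    }
    children <- list()
    for (m in mods) {
      is_motif <- m$node_count == 3L && m$edge_count == 3L
      kids <- if (is_motif) {
        list()
      } else {
        recurse(induced_subgraph(net, m$members), level + 1L)
      }
      children[[length(children) + 1L]] <-
        list(module = m, level = level, children = kids)
    }
    children
  }
  structure(
    list(
      node_count = length(net$nodes),
      edge_count = nrow(net$edges),
      children = recurse(net, 1L)
    ),
    class = "module_hierarchy"
  )
}

#' @export
print.module_hierarchy <- function(x, ...) {
  prof <- hierarchy_flatten(x)
  cat(sprintf(
    "<module_hierarchy> root %d nodes / %d edges; %d modules over %d level(s)\n",
    x$node_count, x$edge_count, nrow(prof),
    if (nrow(prof)) max(prof$level) else 0L
  ))
  invisible(x)
}

#' Flatten a module hierarchy to a table
#'
#' @param h a `module_hierarchy`.
#' @return data.frame with `module_id` (dotted path such as `"1.2"`),
#'   `level`, `nodes`, `edges`, `density`, `mcode_score`.
#' @export
hierarchy_flatten <- function(h) {
  rows <- list()
  walk <- function(children, prefix) {
    for (i in seq_along(children)) {
      entry <- children[[i]]
      id <- if (nzchar(prefix)) paste0(prefix, ".", i) else as.character(i)
      rows[[length(rows) + 1L]] <<- data.frame(
        module_id = id,
        level = entry$level,
        nodes = entry$module$node_count,
        edges = entry$module$edge_count,
        density = entry$module$density,
        mcode_score = entry$module$mcode_score,
        stringsAsFactors = FALSE
      )
      walk(entry$children, id)
    }
  }
  walk(h$children, "")
  if (!length(rows)) {
    return(data.frame(
      module_id = character(0), level = integer(0), nodes = integer(0),
      edges = integer(0), density = numeric(0), mcode_score = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Annotate modules with seed genes
#'
#' Fills each module's `seed_genes` with the intersection of its members
#' and the seed map, and summarizes retention: seeds present in the
#' network (or, if no network is given, in any module) are *retained*,
#' the rest are reported as *not retained*.
#'
#' @param modules list of `mcode_module`.
#' @param seeds named character vector, gene symbol -> `"up"`/`"down"`
#'   (see [seed_labels()]), or an unnamed character vector of symbols.
#' @param network_nodes optional character vector of the parent
#'   network's nodes, used to decide retention.
#' @return The module list with `seed_genes` filled; attribute
#'   `"seed_summary"` holds `per_module` counts, `total` (distinct seeds
#'   in any module), `retained` and `not_retained` symbol vectors.
#' @export
annotate_seed_genes <- function(modules, seeds, network_nodes = NULL) {
  syms <- if (is.null(names(seeds))) {
    toupper(as.character(seeds))
  } else {
    toupper(names(seeds))
  }
  syms <- sort(unique(syms))
  for (i in seq_along(modules)) {
    modules[[i]]$seed_genes <- intersect(modules[[i]]$members, syms)
  }
  in_modules <- sort(unique(unlist(
    lapply(modules, function(m) m$seed_genes)
  )))
  universe <- if (is.null(network_nodes)) in_modules else toupper(network_nodes)
  retained <- intersect(syms, universe)
  attr(modules, "seed_summary") <- list(
    per_module = vapply(modules, function(m) {
      length(m$seed_genes)
    }, integer(1)),
    total = length(in_modules),
    retained = retained,
    not_retained = setdiff(syms, retained)
  )
  modules
}

#' Module list as a table
#'
#' @param modules list of `mcode_module` (ideally after
#'   [annotate_seed_genes()]).
#' @return data.frame with `module_id`, `nodes`, `edges`, `seed_count`,
#'   `seed_genes` (comma-separated), `mcode_score`.
#' @export
module_table <- function(modules) {
  data.frame(
    module_id = seq_along(modules),
    nodes = vapply(modules, function(m) m$node_count, integer(1)),
    edges = vapply(modules, function(m) m$edge_count, integer(1)),
    seed_count = vapply(modules, function(m) {
      length(m$seed_genes)
    }, integer(1)),
    seed_genes = vapply(modules, function(m) {
      paste(m$seed_genes, collapse = ",")
    }, character(1)),
    mcode_score = vapply(modules, function(m) m$mcode_score, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a module table
#' @param modules list of `mcode_module`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(modules, path) {
  tbl <- module_table(modules)
  tbl$mcode_score <- sprintf("%.4f", tbl$mcode_score)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a module hierarchy as nested JSON
#' @param h a `module_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy_json <- function(h, path) {
  strip <- function(children) {
    lapply(children, function(entry) {
      list(
        level = entry$level,
        members = entry$module$members,
        nodes = entry$module$node_count,
        edges = entry$module$edge_count,
        density = entry$module$density,
        mcode_score = entry$module$mcode_score,
        he = entry$module$he,
        children = strip(entry$children)
      )
    })
  }
  jsonlite::write_json(
    list(
      root = list(nodes = h$node_count, edges = h$edge_count),
      children = strip(h$children)
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
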