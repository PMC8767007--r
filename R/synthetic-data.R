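#' Synthetic multi-series DEG tables and interaction networks
#'
#' Every downstream stage of the pipeline is validated against data with
#' known planted structure.  [gen_deg_series()] emulates a panel of
#' differential-expression series from two disease conditions with a
#' chosen number of shared up-/down-regulated genes planted across all
#' series; [gen_ppin()] emulates a scale-free interaction network with
#' fully connected modules planted on designated seed genes.  The same
#' `rng_seed` always reproduces byte-identical output.
#'
#' @name synthetic_data
NULL

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate per-series DEG tables with planted shared genes
#'
#' Two conditions (tags `cond_names`, default `"A"` and `"B"`) with
#' `n_series_a` and `n_series_b` series.  `n_shared_up` genes are planted
#' up-regulated and `n_shared_down` down-regulated in *every* series of
#' *both* conditions: their p-values fall below `p_signal` and their
#' fold changes inside `lfc_signal_range` with concordant sign, so they
#' pass the default filter in every series and are recovered exactly by
#' the overlap stage.  All remaining genes are decoys, split 40/30/30
#' into three rejection paths: p-value above 0.05 everywhere; significant
#' p but fold change outside the \[0.5, 2\] band everywhere; and genes
#' significant in only one condition (concordant there, null in the
#' other), which exercise the intersection logic.
#'
#' Defaults mirror a realistic cardio-renal panel: 6 + 5 series and
#' 19 + 24 planted shared genes out of 2500.
#'
#' @param n_series_a,n_series_b series counts per condition.
#' @param n_genes total genes per series.
#' @param n_shared_up,n_shared_down planted shared gene counts.
#' @param p_signal upper bound for signal p-values (must be < 0.05);
#'   null p-values are drawn uniform on (0.05, 1), signal p-values
#'   uniform on (1e-6, `p_signal`).
#' @param lfc_signal_range length-2 numeric inside \[0.5, 2\]: the
#'   absolute fold-change band for planted signal.
#' @param rng_seed integer seed; fully determines the output.
#' @param cond_names length-2 character: condition tags.
#' @param symbols optional character vector of `n_genes` symbols;
#'   defaults to synthetic identifiers `G000001...` to avoid collision
#'   with real genes.
#' @return List with `tables` (one DEG data.frame per series, columns
#'   `gene logFC pvalue series condition`) and `truth` (a
#'   `synthetic_truth` object: `planted_up_overlap`,
#'   `planted_down_overlap`, `seed_gene_labels`, `rng_seed`).
#' @export
gen_deg_series <- function(n_series_a = 6L, n_series_b = 5L,
                           n_genes = 2500L, n_shared_up = 19L,
                           n_shared_down = 24L, p_signal = 0.01,
                           lfc_signal_range = c(0.5, 2),
                           rng_seed = 1L,
                           cond_names = c("A", "B"),
                           symbols = NULL) {
  n_genes <- as.integer(n_genes)
  n_shared_up <- as.integer(n_shared_up)
  n_shared_down <- as.integer(n_shared_down)
  if (n_shared_up + n_shared_down > n_genes) {
    stop("n_shared_up + n_shared_down exceeds n_genes", call. = FALSE)
  }
  if (n_series_a < 1L || n_series_b < 1L) {
    stop("need at least one series per condition", call. = FALSE)
  }
  if (!(p_signal > 0 && p_signal < 0.05)) {
    stop("p_signal must lie in (0, 0.05)", call. = FALSE)
  }
  if (length(lfc_signal_range) != 2L ||
    lfc_signal_range[1L] < 0.5 || lfc_signal_range[2L] > 2 ||
    lfc_signal_range[1L] > lfc_signal_range[2L]) {
    stop("lfc_signal_range must be an interval inside [0.5, 2]",
      call. = FALSE
    )
  }
  if (is.null(symbols)) {
    symbols <- sprintf("G%06d", seq_len(n_genes))
  } else {
    symbols <- toupper(trimws(symbols))
    if (length(symbols) != n_genes || anyDuplicated(symbols)) {
      stop("symbols must be ", n_genes, " unique identifiers",
        call. = FALSE
      )
    }
  }

  .with_seed(rng_seed, {
    perm <- sample.int(n_genes)
    up_idx <- perm[seq_len(n_shared_up)]
    down_idx <- perm[n_shared_up + seq_len(n_shared_down)]
    decoy_idx <- perm[-seq_len(n_shared_up + n_shared_down)]
    nd <- length(decoy_idx)
    # 40/30/30 split over the three rejection paths
    n_fail_p <- round(0.4 * nd)
    n_fail_lfc <- round(0.3 * nd)
    fail_p_idx <- decoy_idx[seq_len(n_fail_p)]
    fail_lfc_idx <- decoy_idx[n_fail_p + seq_len(n_fail_lfc)]
    one_cond_idx <- decoy_idx[-seq_len(n_fail_p + n_fail_lfc)]
    one_cond_home <- sample(cond_names, length(one_cond_idx), replace = TRUE)
    one_cond_sign <- sample(c(-1, 1), length(one_cond_idx), replace = TRUE)

    sig_p <- function(k) stats::runif(k, 1e-6, p_signal)
    null_p <- function(k) stats::runif(k, 0.05, 1)
    sig_lfc <- function(k) {
      stats::runif(k, lfc_signal_range[1L], lfc_signal_range[2L])
    }
    off_lfc <- function(k) {
      # outside the [0.5, 2] band: too small or too large, random sign
      mag <- ifelse(stats::runif(k) < 0.5,
        stats::runif(k, 0.01, 0.49),
        stats::runif(k, 2.01, 4)
      )
      mag * sample(c(-1, 1), k, replace = TRUE)
    }

    series_ids <- c(
      sprintf("S%s%d", cond_names[1L], seq_len(n_series_a)),
      sprintf("S%s%d", cond_names[2L], seq_len(n_series_b))
    )
    series_cond <- c(
      rep(cond_names[1L], n_series_a),
      rep(cond_names[2L], n_series_b)
    )
    tables <- vector("list", length(series_ids))
    names(tables) <- series_ids
    for (s in seq_along(series_ids)) {
      cond <- series_cond[s]
      lfc <- numeric(n_genes)
      pv <- numeric(n_genes)
      lfc[up_idx] <- sig_lfc(n_shared_up)
      pv[up_idx] <- sig_p(n_shared_up)
      lfc[down_idx] <- -sig_lfc(n_shared_down)
      pv[down_idx] <- sig_p(n_shared_down)
      lfc[fail_p_idx] <- stats::runif(n_fail_p, -2, 2)
      pv[fail_p_idx] <- null_p(n_fail_p)
      lfc[fail_lfc_idx] <- off_lfc(n_fail_lfc)
      pv[fail_lfc_idx] <- sig_p(n_fail_lfc)
      home <- one_cond_home == cond
      k_home <- sum(home)
      k_away <- sum(!home)
      lfc[one_cond_idx[home]] <- one_cond_sign[home] * sig_lfc(k_home)
      pv[one_cond_idx[home]] <- sig_p(k_home)
      lfc[one_cond_idx[!home]] <- stats::runif(k_away, -2, 2)
      pv[one_cond_idx[!home]] <- null_p(k_away)
      tables[[s]] <- data.frame(
        gene = symbols,
        logFC = round(lfc, 6),
        pvalue = signif(pv, 6),
        series = series_ids[s],
        condition = cond,
        stringsAsFactors = FALSE
      )
    }

    labels <- c(
      stats::setNames(rep("up", n_shared_up), symbols[up_idx]),
      stats::setNames(rep("down", n_shared_down), symbols[down_idx])
    )
    truth <- structure(
      list(
        planted_up_overlap = sort(symbols[up_idx]),
        planted_down_overlap = sort(symbols[down_idx]),
        planted_modules = list(),
        seed_gene_labels = labels[sort(names(labels))],
        rng_seed = as.integer(rng_seed)
      ),
      class = "synthetic_truth"
    )
    list(tables = tables, truth = truth)
  })
}

#' Generate a scale-free network with planted dense modules
#'
#' A preferential-attachment backbone (each new node attaches to
#' `attach_m` distinct existing nodes with probability proportional to
#' degree) plus one fully connected clique per entry of `clique_sizes`.
#' Each clique is wired to the backbone through its own dedicated
#' connector node of degree exactly 2 (one edge to a backbone node, one
#' to a clique member), so the planted modules stay separable: the
#' connector's neighbourhood is a path with no 2-core and its MCODE
#' vertex weight is 0, which stops complex traversal at the bridge.
#' Seed genes, if given, are used as the names of clique members (filled
#' clique by clique); `length(seed_genes)` must not exceed the total
#' clique capacity.
#'
#' @param n_nodes total node count (backbone + cliques + connectors).
#' @param attach_m edges added per backbone node (must be < `n_nodes`).
#' @param clique_sizes integer vector of planted clique sizes (each >= 3);
#'   may be empty for a pure preferential-attachment graph.
#' @param seed_genes character vector of symbols to place inside cliques.
#' @param rng_seed integer seed; fully determines the edge list.
#' @return List with `network` (a [gene_network]) and `truth`
#'   (`synthetic_truth` with `planted_modules` = list of clique member
#'   sets).
#' @export
gen_ppin <- function(n_nodes = 500L, attach_m = 2L,
                     clique_sizes = c(8L, 6L, 5L),
                     seed_genes = character(0), rng_seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  attach_m <- as.integer(attach_m)
  clique_sizes <- as.integer(clique_sizes)
  if (attach_m >= n_nodes) stop("attach_m must be < n_nodes", call. = FALSE)
  if (attach_m < 1L) stop("attach_m must be >= 1", call. = FALSE)
  if (length(clique_sizes) && any(clique_sizes < 3L)) {
    stop("every planted clique needs >= 3 nodes", call. = FALSE)
  }
  n_clique <- sum(clique_sizes)
  n_conn <- length(clique_sizes)
  n_backbone <- n_nodes - n_clique - n_conn
  if (n_backbone < attach_m + 1L) {
    stop("n_nodes too small for the requested cliques and backbone",
      call. = FALSE
    )
  }
  seed_genes <- toupper(trimws(as.character(seed_genes)))
  if (length(seed_genes) > n_clique) {
    stop("more seed_genes than clique capacity", call. = FALSE)
  }

  .with_seed(rng_seed, {
    backbone <- sprintf("N%05d", seq_len(n_backbone))
    # preferential attachment: seed with a complete graph on m+1 nodes,
    # then attach each new node to attach_m distinct degree-weighted picks
    m0 <- attach_m + 1L
    from <- character(0)
    to <- character(0)
    deg <- stats::setNames(integer(n_backbone), backbone)
    init <- utils::combn(m0, 2L)
    from <- backbone[init[1L, ]]
    to <- backbone[init[2L, ]]
    deg[seq_len(m0)] <- m0 - 1L
    for (v in (if (n_backbone > m0) seq.int(m0 + 1L, n_backbone) else integer(0))) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, attach_m,
        prob = deg[existing] + 1e-9
      )
      from <- c(from, rep(backbone[v], attach_m))
      to <- c(to, backbone[targets])
      deg[v] <- attach_m
      deg[targets] <- deg[targets] + 1L
    }

    modules <- list()
    slots <- seed_genes
    for (k in seq_along(clique_sizes)) {
      size <- clique_sizes[k]
      take <- min(length(slots), size)
      members <- character(size)
      if (take) {
        members[seq_len(take)] <- slots[seq_len(take)]
        slots <- slots[-seq_len(take)]
      }
      if (take < size) {
        members[(take + 1L):size] <- sprintf(
          "Q%02dM%02d", k, seq.int(take + 1L, size)
        )
      }
      pairs <- utils::combn(size, 2L)
      from <- c(from, members[pairs[1L, ]])
      to <- c(to, members[pairs[2L, ]])
      # degree-2 connector bridging the clique into the backbone
      conn <- sprintf("X%02d", k)
      anchor <- sample(backbone, 1L)
      port <- sample(members, 1L)
      from <- c(from, conn, conn)
      to <- c(to, anchor, port)
      modules[[k]] <- sort(members)
    }

    labels <- stats::setNames(
      rep(NA_character_, length(seed_genes)), seed_genes
    )
    truth <- structure(
      list(
        planted_up_overlap = character(0),
        planted_down_overlap = character(0),
        planted_modules = modules,
        seed_gene_labels = labels,
        rng_seed = as.integer(rng_seed)
      ),
      class = "synthetic_truth"
    )
    list(network = gene_network(from, to), truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d up + %d down planted genes, %d planted modules (seed %d)\n",
    length(x$planted_up_overlap), length(x$planted_down_overlap),
    length(x$planted_modules), x$rng_seed
  ))
  invisible(x)
}

#' Serialize a synthetic truth object as JSON
#' @param truth `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      planted_up_overlap = truth$planted_up_overlap,
      planted_down_overlap = truth$planted_down_overlap,
      planted_modules = truth$planted_modules,
      seed_gene_labels = as.list(truth$seed_gene_labels),
      rng_seed = truth$rng_seed
    ),
    path,
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}
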