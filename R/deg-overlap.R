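#' Differential-expression tables and cross-condition overlap
#'
#' A DEG table is a data.frame with columns `gene` (symbol), `logFC`
#' (log2 fold change), `pvalue`, `series` (accession-like identifier) and
#' `condition` (one of two condition tags, e.g. the two diseases being
#' compared).  These functions filter per-series tables by significance
#' and fold-change thresholds, form per-condition unions, and intersect
#' the two conditions to nominate shared up- and down-regulated genes.
#'
#' @name deg_overlap
NULL

#' Read a DEG table
#'
#' Tab-separated with header `gene logFC pvalue series condition`.
#'
#' @param path file path.
#' @return data.frame with the five columns; symbols uppercased.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "logFC", "pvalue", "series", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("DEG table ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df$gene <- toupper(trimws(df$gene))
  df[need]
}

#' Write a DEG table
#' @param df DEG data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Collapse multiple probe-level records to one record per gene and series
#'
#' Microarray platforms report several probes per gene; after mapping
#' probe ids to symbols a gene may appear several times in one series.
#' Among duplicates the record with maximal `|logFC|` is kept.  Symbols
#' are uppercased and stripped of surrounding whitespace first, so
#' `"Myc"` and `"MYC"` collapse together.
#'
#' @param records DEG data.frame.
#' @return DEG data.frame with one row per (gene, series).
#' @export
collapse_probes <- function(records) {
  if (!nrow(records)) {
    return(records)
  }
  records$gene <- toupper(trimws(records$gene))
  ord <- order(records$gene, records$series, -abs(records$logFC))
  records <- records[ord, ]
  keep <- !duplicated(records[c("gene", "series")])
  out <- records[keep, ]
  rownames(out) <- NULL
  out
}

#' Filter DEGs by p-value and fold-change window
#'
#' A gene is *up* when `pvalue < p_max` and `lfc_low <= logFC <= lfc_high`;
#' *down* when `pvalue < p_max` and `-lfc_high <= logFC <= -lfc_low`.
#' The p-value cut is strict; the fold-change band is closed at both
#' ends.  Raw (unadjusted) p-values are expected: in small multi-platform
#' series, multiplicity adjustment can leave no significant genes at all,
#' so screening is done on raw p with the fold-change band as the main
#' index.  The upper bound excludes extreme fold changes by design; pass
#' `lfc_high = Inf` to disable it.
#'
#' @param records DEG data.frame (ideally after [collapse_probes()]).
#' @param p_max strict p-value cutoff (default 0.05).
#' @param lfc_low,lfc_high closed absolute fold-change window
#'   (defaults 0.5 and 2).
#' @return List with character vectors `up` and `down` (sorted, unique).
#' @export
filter_degs <- function(records, p_max = 0.05, lfc_low = 0.5,
                        lfc_high = 2) {
  if (!(lfc_low > 0 && lfc_low <= lfc_high)) {
    stop("need 0 < lfc_low <= lfc_high", call. = FALSE)
  }
  if (!nrow(records)) {
    return(list(up = character(0), down = character(0)))
  }
  sig <- records$pvalue < p_max
  up <- sig & records$logFC >= lfc_low & records$logFC <= lfc_high
  down <- sig & records$logFC <= -lfc_low & records$logFC >= -lfc_high
  list(
    up = sort(unique(records$gene[up])),
    down = sort(unique(records$gene[down]))
  )
}

#' Build per-condition up/down sets and their unions
#'
#' Splits the input by condition and series, filters each series with
#' [filter_degs()], and forms the per-condition unions of the up- and
#' down-sets.  Thresholds may be overridden per series (different
#' platforms often justify different fold-change windows).
#'
#' @param tables a DEG data.frame, or a list of DEG data.frames which are
#'   row-bound first.
#' @param p_max,lfc_low,lfc_high global thresholds (see [filter_degs()]).
#' @param per_series optional named list: `series id -> list(p_max=,
#'   lfc_low=, lfc_high=)` overriding the global thresholds for that
#'   series (missing entries fall back to the global value).
#' @param conditions optional length-2 character vector naming the two
#'   expected condition tags; defaults to the tags present (must be
#'   exactly two unless only one is present).
#' @return Named list (one element per condition), each of class
#'   `condition_sets` with `up_by_series`, `down_by_series`, `up_union`,
#'   `down_union`.
#' @export
build_condition_sets <- function(tables, p_max = 0.05, lfc_low = 0.5,
                                 lfc_high = 2, per_series = NULL,
                                 conditions = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, tables)
  if (!nrow(df)) stop("no DEG records supplied", call. = FALSE)
  if (any(is.na(df$condition) | !nzchar(df$condition))) {
    stop("every series must carry a condition tag", call. = FALSE)
  }
  tags <- sort(unique(df$condition))
  if (!is.null(conditions)) {
    unknown <- setdiff(tags, conditions)
    if (length(unknown)) {
      stop("unknown condition tag(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    tags <- conditions
  }
  out <- lapply(tags, function(tag) {
    sub <- df[df$condition == tag, , drop = FALSE]
    series_ids <- sort(unique(sub$series))
    ups <- list()
    downs <- list()
    for (sid in series_ids) {
      ov <- per_series[[sid]]
      sets <- filter_degs(
        sub[sub$series == sid, , drop = FALSE],
        p_max = if (!is.null(ov$p_max)) ov$p_max else p_max,
        lfc_low = if (!is.null(ov$lfc_low)) ov$lfc_low else lfc_low,
        lfc_high = if (!is.null(ov$lfc_high)) ov$lfc_high else lfc_high
      )
      ups[[sid]] <- sets$up
      downs[[sid]] <- sets$down
    }
    structure(
      list(
        condition = tag,
        up_by_series = ups,
        down_by_series = downs,
        up_union = sort(unique(unlist(ups, use.names = FALSE))),
        down_union = sort(unique(unlist(downs, use.names = FALSE)))
      ),
      class = "condition_sets"
    )
  })
  names(out) <- tags
  out
}

#' Cross-condition overlap of up- and down-regulated genes
#'
#' Intersects the two conditions' up-unions and down-unions.  A gene
#' landing in both overlaps (up in the two conditions *and* down in the
#' two conditions, via different series) is moved to the `discordant` set
#' and removed from both, so `up_overlap` and `down_overlap` are disjoint
#' and `all_overlap` is their disjoint union.
#'
#' @param cond_a,cond_b `condition_sets` objects from
#'   [build_condition_sets()].
#' @return List of class `overlap_result` with `up_overlap`,
#'   `down_overlap`, `all_overlap`, `discordant`, plus the four union
#'   sizes in `summary`.
#' @export
overlap_conditions <- function(cond_a, cond_b) {
  stopifnot(
    inherits(cond_a, "condition_sets"),
    inherits(cond_b, "condition_sets")
  )
  up <- intersect(cond_a$up_union, cond_b$up_union)
  down <- intersect(cond_a$down_union, cond_b$down_union)
  disc <- intersect(up, down)
  up <- sort(setdiff(up, disc))
  down <- sort(setdiff(down, disc))
  structure(
    list(
      up_overlap = up,
      down_overlap = down,
      all_overlap = sort(c(up, down)),
      discordant = sort(disc),
      summary = c(
        up_union_a = length(cond_a$up_union),
        down_union_a = length(cond_a$down_union),
        up_union_b = length(cond_b$up_union),
        down_union_b = length(cond_b$down_union),
        up_overlap = length(up),
        down_overlap = length(down),
        discordant = length(disc)
      )
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %d up + %d down = %d shared genes (%d discordant)\n",
    length(x$up_overlap), length(x$down_overlap),
    length(x$all_overlap), length(x$discordant)
  ))
  invisible(x)
}

#' Serialize an overlap result to JSON
#'
#' Writes the gene sets plus a Venn-count summary (the four union sizes,
#' the two overlap sizes, and the discordant count).
#'
#' @param res `overlap_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(res, path) {
  jsonlite::write_json(
    list(
      up_overlap = res$up_overlap,
      down_overlap = res$down_overlap,
      all_overlap = res$all_overlap,
      discordant = res$discordant,
      venn_counts = as.list(res$summary)
    ),
    path,
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' Seed-gene direction labels from an overlap result
#'
#' @param res `overlap_result`.
#' @return Named character vector: gene symbol -> `"up"` or `"down"`.
#' @export
seed_labels <- function(res) {
  stopifnot(inherits(res, "overlap_result"))
  labels <- c(
    stats::setNames(rep("up", length(res$up_overlap)), res$up_overlap),
    stats::setNames(rep("down", length(res$down_overlap)), res$down_overlap)
  )
  labels[sort(names(labels))]
}
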