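rec <- function(gene, logFC, pvalue, series = "S1", condition = "A") {
  data.frame(
    gene = gene, logFC = logFC, pvalue = pvalue,
    series = series, condition = condition, stringsAsFactors = FALSE
  )
}

test_that("collapse_probes keeps the max-|logFC| record per gene and series", {
  df <- rbind(
    rec("GENE1", 0.6, 0.01),
    rec("GENE1", -1.4, 0.02),
    rec("Myc", 1.0, 0.01),
    rec("MYC", 0.2, 0.03),
    rec("GENE1", 0.9, 0.01, series = "S2")
  )
  out <- collapse_probes(df)
  expect_equal(nrow(out), 3L)
  expect_equal(out$logFC[out$gene == "GENE1" & out$series == "S1"], -1.4)
  expect_equal(out$logFC[out$gene == "MYC"], 1.0)
  # no duplicates: unchanged content
  clean <- rec(c("A1", "B1"), c(1, -1), c(0.01, 0.01))
  expect_equal(collapse_probes(clean), clean)
})

test_that("filter_degs applies the strict p cut and closed fold-change band", {
  df <- rbind(
    rec("UP1", 1.0, 0.01),
    rec("DN1", -0.6, 0.04),
    rec("HIGH", 2.5, 0.001), # above the band
    rec("NSIG", 1.0, 0.06), # fails p
    rec("EDGE_LO", 0.5, 0.01), # band is closed
    rec("EDGE_HI", -2.0, 0.01),
    rec("PEQ", 1.0, 0.05) # p cut is strict
  )
  sets <- filter_degs(df)
  expect_setequal(sets$up, c("UP1", "EDGE_LO"))
  expect_setequal(sets$down, c("DN1", "EDGE_HI"))
  # disabling the upper bound admits extreme fold changes
  expect_true("HIGH" %in% filter_degs(df, lfc_high = Inf)$up)
  empty <- filter_degs(df[0, ])
  expect_equal(empty, list(up = character(0), down = character(0)))
  expect_error(filter_degs(df, lfc_low = 0), "lfc_low")
})

test_that("relaxing thresholds never shrinks the up/down sets", {
  set.seed(19)
  df <- rec(
    sprintf("G%03d", 1:300), stats::runif(300, -3, 3),
    stats::runif(300)
  )
  strict <- filter_degs(df, p_max = 0.03, lfc_low = 0.7, lfc_high = 1.5)
  loose <- filter_degs(df, p_max = 0.07, lfc_low = 0.5, lfc_high = 2.5)
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))
})

test_that("build_condition_sets unions per-series sets and honours overrides", {
  tabs <- rbind(
    rec(c("A1", "B1"), c(1, 1), 0.01, series = "S1", condition = "X"),
    rec(c("B1", "C1"), c(1, 1), 0.01, series = "S2", condition = "X"),
    rec("D1", 1.8, 0.01, series = "T1", condition = "Y")
  )
  sets <- build_condition_sets(tabs)
  expect_setequal(sets$X$up_union, c("A1", "B1", "C1"))
  expect_equal(sets$Y$up_union, "D1")
  # per-series window: S2 widened to catch a 1.8 logFC only there
  tabs2 <- rbind(
    rec("E1", 1.8, 0.01, series = "S1", condition = "X"),
    rec("E1", 1.8, 0.01, series = "S2", condition = "X")
  )
  sets2 <- build_condition_sets(
    tabs2,
    lfc_high = 1.5,
    per_series = list(S2 = list(lfc_high = 2))
  )
  expect_equal(sets2$X$up_by_series$S1, character(0))
  expect_equal(sets2$X$up_by_series$S2, "E1")
  expect_error(
    build_condition_sets(rec("A1", 1, 0.01, condition = "")),
    "condition"
  )
})

test_that("overlap intersects unions and quarantines discordant genes", {
  mk <- function(up, down, tag) {
    structure(
      list(
        condition = tag,
        up_by_series = list(S = up), down_by_series = list(S = down),
        up_union = up, down_union = down
      ),
      class = "condition_sets"
    )
  }
  a <- mk(c("X1", "Y1", "Z1"), c("E1", "F1"), "A")
  b <- mk(c("Y1", "Z1", "W1"), c("F1", "G1"), "B")
  res <- overlap_conditions(a, b)
  expect_setequal(res$up_overlap, c("Y1", "Z1"))
  expect_equal(res$down_overlap, "F1")
  expect_equal(length(res$all_overlap), 3L)
  # discordant: up in both and down in both
  a2 <- mk(c("Q1", "U1"), "Q1", "A")
  b2 <- mk("Q1", c("Q1", "V1"), "B")
  res2 <- overlap_conditions(a2, b2)
  expect_equal(res2$discordant, "Q1")
  expect_false("Q1" %in% res2$all_overlap)
  expect_equal(
    length(res2$all_overlap),
    length(res2$up_overlap) + length(res2$down_overlap)
  )
})

test_that("overlap recovers exactly the planted sets across seeds", {
  for (s in 1:20) {
    dg <- gen_deg_series(
      n_series_a = 3, n_series_b = 2, n_genes = 300,
      n_shared_up = 5, n_shared_down = 3, rng_seed = s
    )
    sets <- build_condition_sets(lapply(dg$tables, collapse_probes))
    res <- overlap_conditions(sets[[1L]], sets[[2L]])
    expect_identical(res$up_overlap, dg$truth$planted_up_overlap)
    expect_identical(res$down_overlap, dg$truth$planted_down_overlap)
    expect_identical(
      length(res$all_overlap),
      length(res$up_overlap) + length(res$down_overlap)
    )
  }
})

test_that("overlap JSON round-trips the sets and Venn counts", {
  dg <- gen_deg_series(
    n_series_a = 2, n_series_b = 2, n_genes = 100,
    n_shared_up = 4, n_shared_down = 2, rng_seed = 5
  )
  sets <- build_condition_sets(lapply(dg$tables, collapse_probes))
  res <- overlap_conditions(sets[[1L]], sets[[2L]])
  tmp <- withr::local_tempfile(fileext = ".json")
  write_overlap_json(res, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$up_overlap, res$up_overlap)
  expect_equal(back$venn_counts$up_overlap, 4L)
  labels <- seed_labels(res)
  expect_equal(sum(labels == "up"), 4L)
  expect_equal(sum(labels == "down"), 2L)
})
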