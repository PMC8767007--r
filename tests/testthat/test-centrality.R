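# frozen expected values below were derived by hand or with the
# enumeration oracle in helper-graphs.R before being asserted

test_that("degree, neighborhood connectivity and H-index on canonical graphs", {
  p3 <- path_net(3) # A-B-C
  expect_equal(degree_centrality(p3), c(A = 1L, B = 2L, C = 1L))
  expect_equal(neighborhood_connectivity(p3), c(A = 2, B = 1, C = 2))
  expect_equal(h_index(p3), c(A = 1L, B = 1L, C = 1L))

  s5 <- star_net(5)
  expect_equal(unname(degree_centrality(s5)["HUB"]), 5L)
  expect_equal(unname(neighborhood_connectivity(s5)["HUB"]), 1)
  expect_equal(unname(neighborhood_connectivity(s5)["L01"]), 5)
  expect_equal(unname(h_index(s5)["HUB"]), 1L)

  k5 <- complete_net(5)
  expect_equal(unname(degree_centrality(k5)), rep(4L, 5))
  expect_equal(unname(h_index(k5)["A"]), 4L)

  # neighbor degrees {3,3,2,1}: h=3 fails, h=2 holds
  net <- gene_network(
    c("V", "V", "V", "V", "B", "B", "C", "C"),
    c("B", "C", "D", "E", "P1", "D", "Q1", "Q2")
  )
  expect_equal(sort(unname(network_degrees(net)[c("B", "C", "D", "E")])), c(1L, 2L, 3L, 3L))
  expect_equal(unname(h_index(net)["V"]), 2L)
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  expect_equal(
    betweenness_centrality(path_net(3)),
    c(A = 0, B = 1, C = 0)
  )
  # C4: both opposite pairs have two geodesics -> 0.5 per node (derived
  # by enumerating both geodesics of each opposite pair)
  expect_equal(unname(betweenness_centrality(cycle_net(4))), rep(0.5, 4))
  expect_equal(unname(betweenness_centrality(complete_net(5))), rep(0, 5))
})

test_that("local H-index follows the closed-neighbourhood sum", {
  p3 <- path_net(3) # all h = 1
  expect_equal(local_h_index(p3), c(A = 2, B = 3, C = 2))
  k4 <- complete_net(4) # all h = 3 -> 3 + 3*3
  expect_equal(unname(local_h_index(k4)), rep(12, 4))
  iso <- gene_network("A", "B", nodes = "Z")
  expect_equal(unname(local_h_index(iso)["Z"]), 0)
})

test_that("second-order lh mode computes an H-index of neighbour H-indices", {
  cfg <- score_config(lh_mode = "second_order")
  k4 <- complete_net(4) # neighbour h-values {3,3,3} -> h = 3
  expect_equal(unname(local_h_index(k4, cfg)), rep(3, 4))
  expect_equal(unname(local_h_index(star_net(5), cfg)["HUB"]), 1)
})

test_that("clusterrank applies the clustering penalty", {
  # K3: c = 1, f = 10^-1, sum of (2+1) over 2 neighbours = 6 -> 0.6
  expect_equal(unname(clusterrank(complete_net(3))), rep(0.6, 3))
  # star centre: c = 0, five leaves of degree 1 -> 5 * (1+1) = 10
  expect_equal(unname(clusterrank(star_net(5))["HUB"]), 10)
  # degree < 2 convention: c = 0, no penalty
  expect_equal(unname(clusterrank(path_net(2))), c(2, 2))
  # configurable base
  cfg <- score_config(clusterrank_base = 2)
  expect_equal(unname(clusterrank(complete_net(3), cfg)), rep(3, 3))
})

test_that("collective influence counts the exact-distance frontier", {
  cfg1 <- score_config(ci_radius = 1)
  expect_equal(unname(collective_influence(complete_net(3), cfg1)), rep(2, 3))
  expect_equal(unname(collective_influence(star_net(5), cfg1)), rep(0, 6))
  p4 <- path_net(4) # node B at d=1 sees A (deg 1) and C (deg 2)
  expect_equal(unname(collective_influence(p4, cfg1)["B"]), 1)
  # d beyond the diameter: zero everywhere
  cfg9 <- score_config(ci_radius = 9)
  set.seed(5)
  net <- gnp_connected(12, 0.4)
  expect_true(all(collective_influence(net, cfg9) == 0))
})

test_that("all_centralities equals the per-operation results on random graphs", {
  set.seed(11)
  cfg <- score_config()
  for (i in 1:50) {
    net <- gnp_net(sample(4:25, 1), stats::runif(1, 0.1, 0.6))
    ct <- all_centralities(net, cfg)
    expect_equal(ct$dc, unname(degree_centrality(net)))
    expect_equal(ct$bc, unname(betweenness_centrality(net)))
    expect_equal(ct$nc, unname(neighborhood_connectivity(net)))
    expect_equal(ct$h, unname(h_index(net)))
    expect_equal(ct$lh, unname(local_h_index(net, cfg)))
    expect_equal(ct$cr, unname(clusterrank(net, cfg)))
    expect_equal(ct$ci, unname(collective_influence(net, cfg)))
  }
})

test_that("h <= dc and lh >= h on every node of random graphs", {
  set.seed(23)
  for (i in 1:20) {
    net <- gnp_net(sample(5:40, 1), stats::runif(1, 0.05, 0.5))
    ct <- all_centralities(net)
    expect_true(all(ct$h <= ct$dc))
    expect_true(all(ct$lh >= ct$h))
  }
})

test_that("vertex-transitive graphs have constant centralities", {
  for (net in list(cycle_net(6), complete_net(5))) {
    ct <- all_centralities(net)
    for (col in c("dc", "bc", "nc", "h", "lh", "cr", "ci")) {
      expect_length(unique(ct[[col]]), 1L)
    }
  }
})

test_that("centralities are label-invariant", {
  set.seed(31)
  net <- gnp_net(15, 0.3)
  nodes <- network_nodes(net)
  map <- stats::setNames(sprintf("Z%03d", sample(length(nodes))), nodes)
  ct <- all_centralities(net)
  ct2 <- all_centralities(relabel_net(net, map))
  # compare through the map: row for map[v] must equal row for v
  idx <- match(unname(map[ct$node]), ct2$node)
  for (col in c("dc", "bc", "nc", "h", "lh", "cr", "ci")) {
    expect_equal(ct2[[col]][idx], ct[[col]])
  }
})

test_that("betweenness agrees with the enumeration oracle on small random graphs", {
  set.seed(17)
  for (i in 1:30) {
    net <- gnp_net(sample(4:8, 1), stats::runif(1, 0.2, 0.8))
    expect_equal(
      betweenness_centrality(net), oracle_betweenness_enum(net),
      tolerance = 1e-12
    )
  }
})

test_that("centrality table serialization is sorted and formatted", {
  net <- gene_network(c("B", "C"), c("A", "A"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_centrality_table(all_centralities(net), tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1L], "node\tdc\tbc\tnc\th\tlh\tcr\tci")
  expect_equal(substr(lines[2L], 1, 5), "A\t2\t1")
})
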