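test_that("network construction mirrors cliff partners", {
  net <- build_network(make_cliffs(c("A", "B"), c("B", "C"), "sd"))
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(igraph::components(net$graph)$no, 1)

  net2 <- build_network(make_cliffs(c("A", "C"), c("B", "D"), "sd"))
  expect_equal(igraph::components(net2$graph)$no, 2)

  empty <- build_network(make_cliffs(character(0), character(0),
                                     character(0)))
  expect_equal(igraph::vcount(empty$graph), 0)

  # duplicate cliffs collapse to one edge per compound pair
  dup <- build_network(make_cliffs(c("A", "A"), c("B", "B"), "sd"))
  expect_equal(igraph::ecount(dup$graph), 1)
})

test_that("clusters are multi-node components; pairs are isolated", {
  cl <- find_clusters(build_network(make_cliffs(c("A", "B"), c("B", "C"),
                                                "sd")))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$kind, "cluster")
  expect_identical(cl$n_nodes, 3L)

  cl2 <- find_clusters(build_network(make_cliffs("A", "B", "sd")))
  expect_identical(cl2$kind, "isolated_pair")

  # components partition the nodes
  cliffs <- make_cliffs(c("A", "B", "D", "F"), c("B", "C", "E", "G"), "sd")
  net <- build_network(cliffs)
  cl3 <- find_clusters(net)
  members <- unlist(strsplit(cl3$members, ";", fixed = TRUE))
  expect_setequal(members, c("A", "B", "C", "D", "E", "F", "G"))
  expect_identical(anyDuplicated(members), 0L)
})

test_that("network comparison classifies extended and new clusters", {
  # sd pair {A,B}; inactive I extends it: one extended cluster, none new
  sd_net <- build_network(make_cliffs("A", "B", "sd"))
  comb <- build_network(rbind(make_cliffs("A", "B", "sd"),
                              make_cliffs("B", "I", "isd")))
  cmp <- compare_networks(sd_net, comb)
  expect_identical(cmp$n_extended_clusters, 1L)
  expect_identical(cmp$n_new_clusters, 0L)

  # C forms no sd cliff; two inactive analogs create a new cluster
  sd_net2 <- build_network(make_cliffs("A", "B", "sd"))
  comb2 <- build_network(rbind(make_cliffs("A", "B", "sd"),
                               make_cliffs(c("C", "C"), c("I1", "I2"),
                                           "isd")))
  cmp2 <- compare_networks(sd_net2, comb2)
  expect_identical(cmp2$n_new_clusters, 1L)
  expect_identical(cmp2$n_extended_clusters, 0L)
  expect_identical(cmp2$n_unchanged_components, 1L)

  # no isd cliffs: all-zero deltas
  cmp3 <- compare_networks(sd_net, sd_net)
  expect_identical(cmp3$n_new_clusters, 0L)
  expect_identical(cmp3$n_extended_clusters, 0L)
  expect_identical(cmp3$n_unchanged_components, 1L)

  # an inactive bridging two sd components is an extended, merged cluster
  sd_net4 <- build_network(make_cliffs(c("A", "C"), c("B", "D"), "sd"))
  comb4 <- build_network(rbind(make_cliffs(c("A", "C"), c("B", "D"), "sd"),
                               make_cliffs(c("B", "I"), c("I", "C"),
                                           "isd")))
  cmp4 <- compare_networks(sd_net4, comb4)
  expect_identical(cmp4$n_extended_clusters, 1L)
  expect_identical(cmp4$n_merged_clusters, 1L)

  # combined network missing an sd edge is a consistency error
  expect_error(compare_networks(sd_net4, build_network(
    make_cliffs("A", "B", "sd"))), "missing sd edges")
})

test_that("isd edges connect one active and one inactive node", {
  b <- generate_target_set(generator_config(seed = 31L), "TN")
  pairs <- find_matched_pairs(b$set$actives[, c("compound_id", "smiles")])
  pairs <- pair_potency_deltas(pairs[apply_tsr_filter(pairs), ],
                               b$set$actives)
  thr <- compute_set_threshold(pairs, "TN", "MMP")
  sd_cl <- call_sd_cliffs(pairs, thr)
  acrp <- determine_acrp_compounds(sd_cl, b$set)
  isd <- call_isd_cliffs(acrp, b$set, "MMP")
  expect_gt(nrow(isd), 0L)  # deterministic at this seed (2 isd cliffs)
  net <- build_network(rbind(sd_cl, isd), b$set, acrp)
  g <- net$graph
  st <- igraph::V(g)$status
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e, names = FALSE)
    if (igraph::E(g)$cliff_type[e] == "isd") {
      expect_identical(sort(st[ends]), c("active", "inactive"))
    } else {
      expect_identical(st[ends], c("active", "active"))
    }
  }
  # inactive nodes have only isd-type incident edges and degree >= 1
  inact <- which(st == "inactive")
  expect_true(all(igraph::degree(g)[inact] >= 1))
  for (v in inact) {
    eids <- igraph::incident(g, v)
    expect_true(all(igraph::E(g)$cliff_type[eids] == "isd"))
  }
})

test_that("graph export round-trips through the node/edge tables", {
  net <- build_network(rbind(make_cliffs(c("A", "B"), c("B", "C"), "sd"),
                             make_cliffs("B", "I", "isd")))
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_graph(net, prefix)
  expect_true(all(file.exists(paths)))
  back <- import_graph_tables(prefix)
  expect_identical(igraph::vcount(back$graph), igraph::vcount(net$graph))
  ekey <- function(g) {
    e <- igraph::ends(g, igraph::E(g))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(ekey(back$graph), ekey(net$graph))
  expect_setequal(igraph::V(back$graph)$name, igraph::V(net$graph)$name)

  # empty network exports valid empty files
  enet <- build_network(make_cliffs(character(0), character(0),
                                    character(0)))
  eprefix <- file.path(withr::local_tempdir(), "empty")
  export_graph(enet, eprefix)
  eback <- import_graph_tables(eprefix)
  expect_equal(igraph::vcount(eback$graph), 0)
})
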