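edge_df <- function(a, b, xl = 1L, bn = 0L) {
  data.frame(accession_a = a, accession_b = b, xl_count = xl, bn_count = bn)
}

test_that("evidence merges onto single edges and the blocklist removes nodes", {
  xl <- data.frame(accession_a = c("A", "A"), accession_b = c("B", "UBC"),
                   xl_count = c(2L, 1L))
  bn <- data.frame(accession_a = "A", accession_b = "B",
                   n_replicates_passing = 3L)
  g <- build_network(xl, bn, blocklist = c("UBC"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$xl_count, 2)
  expect_equal(igraph::E(g)$bn_count, 3)
  expect_false("UBC" %in% igraph::V(g)$name)

  empty <- build_network(xl[0, ], NULL)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("second-order interactors obey the one-XL / two-BN rule", {
  # E endosomal; D1, D2 direct interactors; S1..S3 second-order candidates
  edges <- rbind(
    edge_df("E", "D1"), edge_df("E", "D2"),
    edge_df("S1", "D1", xl = 1L),                 # one XL edge: retained
    edge_df("S2", "D1", xl = 0L, bn = 2L),        # one BN edge only: dropped
    edge_df("S3", "D1", xl = 0L, bn = 2L),        # two BN-linked directs: kept
    edge_df("S3", "D2", xl = 0L, bn = 2L),
    edge_df("N1", "D1", xl = 1L)                  # nuclear: removed
  )
  g <- toy_graph(edges)
  out <- endosome_center_filter(g, endosomal = "E", nuclear = "N1")
  kept <- igraph::V(out)$name
  expect_true(all(c("E", "D1", "D2", "S1", "S3") %in% kept))
  expect_false("S2" %in% kept)
  expect_false("N1" %in% kept)

  # alternative reading: one BN edge passing in >= 2 replicates suffices
  alt <- endosome_center_filter(g, endosomal = "E", nuclear = "N1",
                                bn_rule = "two_replicates")
  expect_true("S2" %in% igraph::V(alt)$name)
})

test_that("blocklist and endosome-centering commute", {
  edges <- rbind(
    edge_df("E", "D1"), edge_df("D1", "S1"), edge_df("E", "KRT1"),
    edge_df("KRT1", "D1"))
  ab <- endosome_center_filter(
    build_network(edges[c("accession_a", "accession_b", "xl_count")],
                  blocklist = "KRT1"), endosomal = "E")
  # centering first, then removing the blocklisted node
  g_all <- build_network(edges[c("accession_a", "accession_b", "xl_count")])
  ba0 <- endosome_center_filter(g_all, endosomal = "E")
  ba <- igraph::induced_subgraph(
    ba0, setdiff(igraph::V(ba0)$name, "KRT1"))
  expect_setequal(igraph::V(ab)$name, igraph::V(ba)$name)
  expect_equal(igraph::ecount(ab), igraph::ecount(ba))
})

test_that("core component selection is deterministic under ties", {
  g1 <- igraph::graph_from_literal(A - B, A - C, B - C, C - D, D - A, X - Y, Y - Z)
  expect_setequal(igraph::V(core_component(g1))$name, c("A", "B", "C", "D"))

  conn <- igraph::make_ring(5)
  expect_equal(igraph::vcount(core_component(conn)), 5)

  # tie 4 vs 4 nodes: 5 edges beats 3
  g2 <- igraph::graph_from_data_frame(data.frame(
    from = c("A", "A", "B", "C", "A", "W", "X", "Y"),
    to   = c("B", "C", "C", "D", "D", "X", "Y", "Z")), directed = FALSE)
  expect_setequal(igraph::V(core_component(g2))$name, c("A", "B", "C", "D"))
})

test_that("network statistics match hand-computed values", {
  path3 <- igraph::graph_from_literal(A - B, B - C)
  s <- network_stats(path3)
  expect_equal(s$mean_shortest_path, 4 / 3)  # distances 1, 1, 2 over 3 pairs

  k4 <- igraph::make_full_graph(4)
  expect_equal(network_stats(k4)$mean_shortest_path, 1.0)

  # two-bin degree histogram (star) is perfectly collinear in log-log space
  star <- igraph::make_star(20, mode = "undirected")
  expect_equal(network_stats(star)$powerlaw_r2, 1.0)

  expect_warning(tiny <- network_stats(igraph::make_empty_graph(1, directed = FALSE)),
                 "< 2 nodes")
  expect_true(tiny$degenerate)
})

test_that("preferential-attachment graphs fit a power law better than random ones", {
  for (seed in 1:5) {
    pa <- withr::with_seed(seed, igraph::sample_pa(2000, m = 1, directed = FALSE))
    er <- withr::with_seed(seed, igraph::sample_gnm(2000, igraph::ecount(pa)))
    r2_pa <- network_stats(pa)$powerlaw_r2
    r2_er <- network_stats(er)$powerlaw_r2
    expect_gt(r2_pa, 0.9)
    expect_gt(r2_pa, r2_er)
  }
})

test_that("edge-betweenness communities split obvious structure", {
  two_tri <- igraph::graph_from_literal(A - B, B - C, C - A, D - E, E - F, F - D, C - D)
  part <- detect_communities(two_tri)
  expect_equal(attr(part, "n_communities"), 2L)
  expect_equal(length(unique(part$community[part$accession %in% c("A", "B", "C")])), 1)

  k5 <- igraph::make_full_graph(5)
  expect_equal(attr(detect_communities(k5), "n_communities"), 1L)

  disc <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  pd <- detect_communities(disc)
  expect_equal(attr(pd, "n_communities"), 2L)
})

test_that("rewiring conserves the degree sequence and is seeded", {
  g <- withr::with_seed(1, igraph::sample_gnm(60, 150))
  nulls <- rewire_null(g, n_permutations = 10, seed = 3)
  for (h in nulls) {
    expect_identical(igraph::degree(h), igraph::degree(g))
    expect_true(igraph::is_simple(h))
  }
  nulls2 <- rewire_null(g, n_permutations = 10, seed = 3)
  for (i in seq_along(nulls)) {
    expect_true(igraph::identical_graphs(nulls[[i]], nulls2[[i]]))
  }

  # a 4-cycle's only degree-preserving simple rewirings are 4-cycles
  ring <- igraph::make_ring(4)
  for (h in rewire_null(ring, n_permutations = 5, seed = 1)) {
    expect_identical(igraph::degree(h), igraph::degree(ring))
    expect_true(igraph::is_connected(h) || igraph::ecount(h) == 4)
  }
})

test_that("complex coherence finds planted cliques and bounds empirical p", {
  clique_edges <- t(combn(paste0("C", 1:4), 2))
  bg <- data.frame(from = paste0("B", 1:6),
                   to = c(paste0("B", 2:6), "C1"))
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = clique_edges[, 1], to = clique_edges[, 2]), bg),
    directed = FALSE)
  igraph::E(g)$xl_count <- 1L
  ann <- data.frame(complex_id = "K", accession = paste0("C", 1:4))
  nulls <- rewire_null(g, n_permutations = 100, seed = 2)
  coh <- complex_coherence(g, ann, nulls)
  within_d <- coh$pair_distances$distance[coh$pair_distances$class == "within"]
  expect_true(all(within_d == 1))
  expect_gte(coh$p_value, 1 / 101)
  expect_lte(coh$p_value, 1)

  # single-member complexes are skipped
  coh2 <- complex_coherence(g, data.frame(complex_id = "solo", accession = "C1"),
                            NULL)
  expect_equal(nrow(coh2$neighbor_fraction), 0)
})

test_that("triangle enumeration honours the cross-link requirement", {
  bn_tri <- edge_df(c("A", "B", "A"), c("B", "C", "C"), xl = 0L, bn = 2L)
  g1 <- toy_graph(bn_tri)
  expect_equal(nrow(enumerate_3cliques(g1)), 0)
  expect_equal(nrow(enumerate_3cliques(g1, require_xl = FALSE)), 1)

  one_xl <- edge_df(c("A", "B", "A"), c("B", "C", "C"),
                    xl = c(1L, 0L, 0L), bn = c(0L, 2L, 2L))
  expect_equal(nrow(enumerate_3cliques(toy_graph(one_xl))), 1)

  k4 <- t(combn(LETTERS[1:4], 2))
  g4 <- toy_graph(edge_df(k4[, 1], k4[, 2], xl = 1L))
  tri <- enumerate_3cliques(g4)
  expect_equal(nrow(tri), 4)
  oracle <- brute_triangles(edge_df(k4[, 1], k4[, 2], xl = 1L))
  expect_equal(as.data.frame(tri), oracle, ignore_attr = TRUE)
})

test_that("triangle enumeration equals brute force on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(8:25, 1)
    g <- igraph::sample_gnp(n, 0.25)
    igraph::V(g)$name <- sprintf("P%02d", seq_len(n))
    igraph::E(g)$xl_count <- sample(0:1, igraph::ecount(g), replace = TRUE)
    el <- igraph::as_data_frame(g, "edges")
    edges <- data.frame(accession_a = el$from, accession_b = el$to,
                        xl_count = el$xl_count)
    got <- as.data.frame(enumerate_3cliques(g))
    oracle <- brute_triangles(edges)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

test_that("compartment connectivity tabulates endosomal partners", {
  mk <- function(edges, comps) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(
                                         name = names(comps),
                                         compartment = unname(comps)))
    igraph::E(g)$xl_count <- 1L
    g
  }
  all_endo <- mk(data.frame(from = c("A", "B"), to = c("B", "C")),
                 c(A = "endosome", B = "endosome", C = "endosome"))
  expect_equal(attr(compartment_connectivity(all_endo),
                    "fraction_endo_lyso_golgi"), 1.0)

  star <- mk(data.frame(from = "H", to = c("N1", "N2", "N3")),
             c(H = "endosome", N1 = "nucleus", N2 = "nucleus", N3 = "nucleus"))
  expect_equal(attr(compartment_connectivity(star),
                    "fraction_endo_lyso_golgi"), 0.0)

  # mixed toy, hand-tabulated: partners 2 endo, 1 lysosome, 1 golgi, 1 nucleus
  mixed <- mk(
    data.frame(from = c("E1", "E1", "E1", "E2", "E2", "X1"),
               to = c("E2", "L1", "G1", "N1", "E3", "X2")),
    c(E1 = "endosome", E2 = "endosome", E3 = "endosome", L1 = "lysosome",
      G1 = "golgi", N1 = "nucleus", X1 = "other", X2 = "other"))
  tab <- compartment_connectivity(mixed)
  get <- function(cmp) tab$n_edges[tab$partner_compartment == cmp]
  expect_equal(get("endosome"), 2L)
  expect_equal(get("lysosome"), 1L)
  expect_equal(get("golgi"), 1L)
  expect_equal(get("nucleus"), 1L)
  expect_equal(attr(tab, "fraction_endo_lyso_golgi"), 4 / 5)

  # multi-compartment nodes resolve by endosome-first precedence
  multi <- mk(data.frame(from = "E1", to = "M1"),
              c(E1 = "endosome", M1 = "lysosome,endosome"))
  expect_equal(attr(compartment_connectivity(multi),
                    "fraction_endo_lyso_golgi"), 1.0)
})
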