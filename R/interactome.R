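#' Build the integrated interaction graph from XL and BN evidence
#'
#' Merges cross-link-derived and co-fractionation-derived protein-pair
#' edges into one undirected simple graph; a pair supported by both
#' carries both evidence attributes (`xl_count`,
#' `bn_replicates_passing`). Blocklisted proteins -- by default the spiked
#' native-gel marker proteins, the purification handle, ubiquitin (usually
#' a modification, not a complex member) and keratin contaminants -- are
#' removed with their edges. Self edges are dropped.
#'
#' @param xl_edges Tibble `accession_a`, `accession_b`, `xl_count` (e.g.
#'   from [collapse_to_pairs()]).
#' @param bn_edges Tibble `accession_a`, `accession_b`,
#'   `n_replicates_passing` (e.g. the passing pairs of
#'   [filter_bn_candidates()]), or `NULL`.
#' @param annotations Optional node tibble (`accession` plus attribute
#'   columns such as `compartment`, `is_endosomal`) attached as vertex
#'   attributes.
#' @param blocklist Character vector of accessions to remove.
#' @return An undirected `igraph` with edge attributes `xl_count` and
#'   `bn_count`.
#' @export
build_network <- function(xl_edges, bn_edges = NULL, annotations = NULL,
                          blocklist = character()) {
  xl <- if (!is.null(xl_edges) && nrow(xl_edges) > 0) {
    e <- canonicalize_pairs(as_tibble(xl_edges))
    tibble(accession_a = e$accession_a, accession_b = e$accession_b,
           xl_count = e$xl_count, bn_count = 0L)
  } else {
    tibble(accession_a = character(), accession_b = character(),
           xl_count = integer(), bn_count = integer())
  }
  bn <- if (!is.null(bn_edges) && nrow(bn_edges) > 0) {
    e <- canonicalize_pairs(as_tibble(bn_edges))
    cnt <- if ("n_replicates_passing" %in% names(e)) e$n_replicates_passing
           else e$bn_count
    tibble(accession_a = e$accession_a, accession_b = e$accession_b,
           xl_count = 0L, bn_count = as.integer(cnt))
  } else {
    xl[0, ]
  }
  edges <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(xl, bn), .data$accession_a, .data$accession_b),
    xl_count = sum(.data$xl_count), bn_count = sum(.data$bn_count),
    .groups = "drop"
  )
  edges <- edges[edges$accession_a != edges$accession_b, ]
  edges <- edges[!(edges$accession_a %in% blocklist |
                     edges$accession_b %in% blocklist), ]

  verts <- tibble(name = sort(unique(c(edges$accession_a, edges$accession_b))))
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations)
    names(ann)[names(ann) == "accession"] <- "name"
    verts <- dplyr::left_join(verts, ann, by = "name")
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Center the network on the organelle proteome
#'
#' Retains the endosomal proteins, their direct interactors, and second-order
#' interactors that are connected to at least one direct interactor by a
#' cross-link-supported edge and/or to at least two distinct direct
#' interactors by co-fractionation-only evidence. Exclusively-nuclear
#' proteins (doubtful connectivity) are removed. The result is the induced
#' subgraph on the retained nodes.
#'
#' @param graph igraph from [build_network()].
#' @param endosomal Character vector of endosomal accessions.
#' @param nuclear Character vector of exclusively-nuclear accessions.
#' @param bn_rule `"two_edges"` (default; two distinct BN-connected direct
#'   interactors) or `"two_replicates"` (one BN edge passing in >= 2
#'   replicates).
#' @return Induced igraph subgraph.
#' @export
endosome_center_filter <- function(graph, endosomal, nuclear = character(),
                                   bn_rule = c("two_edges", "two_replicates")) {
  bn_rule <- match.arg(bn_rule)
  if (length(endosomal) == 0) abort("`endosomal` must be non-empty")
  nodes <- igraph::V(graph)$name
  endo <- intersect(nodes, endosomal)
  el <- igraph::as_data_frame(graph, what = "edges")

  neighbors_of <- function(set) {
    hit <- el$from %in% set | el$to %in% set
    setdiff(unique(c(el$from[hit], el$to[hit])), set)
  }
  direct <- setdiff(neighbors_of(endo), endo)
  second <- setdiff(nodes, c(endo, direct))

  keep_second <- vapply(second, function(v) {
    inc <- el[(el$from == v & el$to %in% direct) |
                (el$to == v & el$from %in% direct), , drop = FALSE]
    if (nrow(inc) == 0) return(FALSE)
    if (any(inc$xl_count >= 1)) return(TRUE)
    bn <- inc[inc$bn_count >= 1, , drop = FALSE]
    if (bn_rule == "two_edges") {
      partners <- unique(ifelse(bn$from == v, bn$to, bn$from))
      length(partners) >= 2
    } else {
      any(bn$bn_count >= 2)
    }
  }, logical(1))

  retained <- c(endo, direct, second[keep_second])
  retained <- setdiff(retained, setdiff(intersect(retained, nuclear), endo))
  igraph::induced_subgraph(graph, retained)
}

#' Largest connected component
#'
#' Ties on node count are broken by edge count, then by the
#' lexicographically smallest member accession, so the choice is
#' deterministic.
#'
#' @param graph igraph.
#' @return Induced subgraph of the winning component (empty graph in,
#'   empty graph out).
#' @export
core_component <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(
      graph, "name", value = as.character(seq_len(igraph::vcount(graph))))
  }
  comp <- igraph::components(graph)
  members <- split(igraph::V(graph)$name, comp$membership)
  sizes <- lengths(members)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    ecounts <- vapply(cand, function(i) {
      igraph::ecount(igraph::induced_subgraph(graph, members[[i]]))
    }, numeric(1))
    cand <- cand[ecounts == max(ecounts)]
  }
  if (length(cand) > 1) {
    firsts <- vapply(cand, function(i) min(members[[i]]), character(1))
    cand <- cand[order(firsts)[1]]
  }
  igraph::induced_subgraph(graph, members[[cand[1]]])
}

#' Global network statistics
#'
#' Mean shortest path over connected node pairs (unweighted BFS distances),
#' the degree histogram, and the goodness of fit of a power law to the
#' degree distribution: R-squared of the least-squares line on log degree
#' vs log frequency (degrees >= 1, zero-frequency bins dropped). A
#' maximum-likelihood exponent fit is available behind
#' `powerlaw_method = "mle"`.
#'
#' @param graph igraph.
#' @param powerlaw_method `"ls"` (default) or `"mle"`.
#' @return A `network_stats` list: `n_nodes`, `n_edges`,
#'   `mean_shortest_path`, `powerlaw_r2`, `powerlaw_exponent`,
#'   `degree_histogram` tibble, `degenerate` flag. `glance()` gives a
#'   one-row tibble.
#' @export
network_stats <- function(graph, powerlaw_method = c("ls", "mle")) {
  powerlaw_method <- match.arg(powerlaw_method)
  n <- igraph::vcount(graph)
  out <- list(n_nodes = n, n_edges = igraph::ecount(graph),
              mean_shortest_path = NA_real_, powerlaw_r2 = NA_real_,
              powerlaw_exponent = NA_real_,
              degree_histogram = tibble(degree = integer(), count = integer()),
              degenerate = n < 2)
  class(out) <- "network_stats"
  if (n < 2) {
    warn("graph has < 2 nodes; statistics undefined")
    return(out)
  }
  d <- igraph::distances(graph)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  out$mean_shortest_path <- if (length(vals)) mean(vals) else NA_real_

  deg <- igraph::degree(graph)
  tab <- table(deg[deg >= 1])
  out$degree_histogram <- tibble(degree = as.integer(names(tab)),
                                 count = as.integer(tab))
  if (powerlaw_method == "mle") {
    fit <- igraph::fit_power_law(deg[deg >= 1])
    out$powerlaw_exponent <- fit$alpha
    out$powerlaw_r2 <- NA_real_
  } else if (nrow(out$degree_histogram) >= 2) {
    lx <- log10(out$degree_histogram$degree)
    ly <- log10(out$degree_histogram$count)
    fit <- stats::lm(ly ~ lx)
    out$powerlaw_r2 <- summary(fit)$r.squared
    out$powerlaw_exponent <- -unname(stats::coef(fit)[2])
  }
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "<network_stats: %d nodes, %d edges, mean path %.2f, power-law R2 %.3f>\n",
    x$n_nodes, x$n_edges, x$mean_shortest_path, x$powerlaw_r2))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.network_stats <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
         mean_shortest_path = x$mean_shortest_path,
         powerlaw_r2 = x$powerlaw_r2, powerlaw_exponent = x$powerlaw_exponent,
         degenerate = x$degenerate)
}

#' Edge-betweenness community detection
#'
#' Girvan-Newman hierarchy (iterative removal of the highest-betweenness
#' edge) cut at maximum modularity, computed per connected component. The
#' igraph implementation is deterministic for a given graph.
#'
#' @param graph igraph.
#' @return Tibble `accession`, `community` (integer), with attributes
#'   `"modularity"` and `"n_communities"`.
#' @export
detect_communities <- function(graph) {
  cl <- igraph::cluster_edge_betweenness(graph, weights = NULL)
  out <- tibble(accession = igraph::V(graph)$name,
                community = as.integer(igraph::membership(cl)))
  attr(out, "modularity") <- max(cl$modularity)
  attr(out, "n_communities") <- length(unique(out$community))
  out
}

#' Degree-preserving rewired null graphs
#'
#' Generates `n_permutations` randomized graphs with exactly the input's
#' degree sequence via double-edge swaps that reject self-loops and
#' multi-edges. Graphs with no valid swap (e.g. stars) come back unchanged
#' with a warning. Seeded: each permutation draws from its own substream,
#' so the series is reproducible.
#'
#' @param graph Simple igraph.
#' @param n_permutations Number of null graphs (default 100).
#' @param seed Integer seed.
#' @return List of igraphs.
#' @export
rewire_null <- function(graph, n_permutations = 100L, seed = 1L) {
  n_permutations <- assert_count(n_permutations, "n_permutations")
  if (igraph::ecount(graph) < 2) {
    warn("graph has < 2 edges; no rewiring possible, returning copies")
    return(rep(list(graph), n_permutations))
  }
  niter <- max(100L, 10L * igraph::ecount(graph))
  nulls <- lapply(seq_len(n_permutations), function(i) {
    with_substream(seed, paste0("rewire_", i),
                   igraph::rewire(graph, igraph::keeping_degseq(niter = niter)))
  })
  if (igraph::identical_graphs(nulls[[1]], graph) &&
      igraph::identical_graphs(nulls[[min(2L, n_permutations)]], graph)) {
    warn("rewiring left the graph unchanged (no valid swaps?)")
  }
  nulls
}

#' Complex coherence within the network
#'
#' Compares shortest-path distances of within-complex node pairs against
#' between-complex and unannotated pairs, and computes each annotated
#' protein's fraction of direct neighbours in the same complex. The mean
#' neighbour fraction is tested against degree-preserving rewired nulls:
#' the empirical p-value is `(1 + #{null >= observed}) / (n_null + 1)`,
#' bounded below by `1/(n_null + 1)`.
#'
#' @param graph igraph.
#' @param complexes Tibble `complex_id`, `accession`. Complexes with a
#'   single member present in the graph are skipped.
#' @param nulls List of rewired graphs (see [rewire_null()]), or `NULL`
#'   to skip the null comparison.
#' @return A `complex_coherence` list: `pair_distances` tibble
#'   (`class` in within/between/unannotated, `distance`),
#'   `neighbor_fraction` tibble per protein, `observed_mean`, `null_means`,
#'   `p_value`. `glance()` summarizes.
#' @export
complex_coherence <- function(graph, complexes, nulls = NULL) {
  nodes <- igraph::V(graph)$name
  ann <- as_tibble(complexes)
  ann <- ann[ann$accession %in% nodes, ]
  keep <- dplyr::add_count(ann, .data$complex_id)
  ann <- keep[keep$n > 1, c("complex_id", "accession")]
  membership <- split(ann$complex_id, ann$accession)
  annotated <- names(membership)

  share_complex <- function(a, b) {
    length(intersect(membership[[a]], membership[[b]])) > 0
  }

  d <- igraph::distances(graph)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pa <- nodes[idx[, 1]]; pb <- nodes[idx[, 2]]
  both_ann <- pa %in% annotated & pb %in% annotated
  cls <- character(length(pa))
  cls[!both_ann] <- "unannotated"
  within_flag <- logical(length(pa))
  if (any(both_ann)) {
    within_flag[both_ann] <- mapply(share_complex, pa[both_ann], pb[both_ann])
  }
  cls[both_ann] <- ifelse(within_flag[both_ann], "within", "between")
  pair_distances <- tibble(class = cls, distance = d[upper.tri(d)])
  pair_distances <- pair_distances[is.finite(pair_distances$distance), ]

  mean_neighbor_fraction <- function(g) {
    fr <- vapply(annotated, function(v) {
      if (!v %in% igraph::V(g)$name) return(NA_real_)
      nb <- igraph::neighbors(g, v)$name
      if (length(nb) == 0) return(NA_real_)
      nb_ann <- nb[nb %in% annotated]
      if (length(nb) == 0) return(NA_real_)
      sum(vapply(nb_ann, share_complex, logical(1), a = v)) / length(nb)
    }, numeric(1))
    fr
  }
  obs_fr <- mean_neighbor_fraction(graph)
  observed_mean <- mean(obs_fr, na.rm = TRUE)
  null_means <- if (!is.null(nulls)) {
    vapply(nulls, function(g) mean(mean_neighbor_fraction(g), na.rm = TRUE),
           numeric(1))
  } else {
    numeric(0)
  }
  p_value <- if (length(null_means)) {
    (1 + sum(null_means >= observed_mean)) / (length(null_means) + 1)
  } else {
    NA_real_
  }
  out <- list(
    pair_distances = pair_distances,
    neighbor_fraction = tibble(accession = annotated, fraction = unname(obs_fr)),
    observed_mean = observed_mean, null_means = null_means, p_value = p_value
  )
  class(out) <- "complex_coherence"
  out
}

#' @exportS3Method generics::glance
glance.complex_coherence <- function(x, ...) {
  mean_by <- function(cl) {
    v <- x$pair_distances$distance[x$pair_distances$class == cl]
    if (length(v)) mean(v) else NA_real_
  }
  tibble(
    mean_within_distance = mean_by("within"),
    mean_between_distance = mean_by("between"),
    mean_neighbor_fraction = x$observed_mean,
    null_mean = if (length(x$null_means)) mean(x$null_means) else NA_real_,
    p_value = x$p_value,
    n_nulls = length(x$null_means)
  )
}

#' Enumerate 3-cliques with cross-link support
#'
#' All unordered protein triples whose three edges exist in the graph and
#' of which at least one carries cross-link evidence (`xl_count >= 1`).
#' Triples are reported in canonical (sorted) order, without duplicates.
#'
#' @param graph igraph with edge attribute `xl_count`.
#' @param require_xl Require >= 1 cross-link-supported edge (default TRUE).
#' @return Tibble `accession_a`, `accession_b`, `accession_c`, `n_xl_edges`.
#' @export
enumerate_3cliques <- function(graph, require_xl = TRUE) {
  tri <- igraph::triangles(graph)
  if (length(tri) == 0) {
    return(tibble(accession_a = character(), accession_b = character(),
                  accession_c = character(), n_xl_edges = integer()))
  }
  m <- matrix(igraph::V(graph)$name[tri], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  xl <- igraph::E(graph)$xl_count
  n_xl <- vapply(seq_len(nrow(m)), function(i) {
    eids <- igraph::get_edge_ids(graph, c(m[i, 1], m[i, 2],
                                          m[i, 1], m[i, 3],
                                          m[i, 2], m[i, 3]))
    sum(xl[eids] >= 1)
  }, numeric(1))
  out <- tibble(accession_a = m[, 1], accession_b = m[, 2],
                accession_c = m[, 3], n_xl_edges = as.integer(n_xl))
  if (require_xl) out <- out[out$n_xl_edges >= 1, ]
  dplyr::arrange(out, .data$accession_a, .data$accession_b, .data$accession_c)
}

#' Cross-tabulate edges by node compartment
#'
#' For every edge incident to at least one endosomal node, tabulates the
#' partner's compartment and reports the fraction of endosomal interactions
#' whose partner is endosomal, lysosomal or Golgi. Multi-compartment nodes
#' resolve by fixed precedence (endosome > lysosome > golgi > mitochondria >
#' nucleus > other) so no edge is double counted.
#'
#' @param graph igraph whose vertices carry a `compartment` attribute
#'   (single label or comma-separated set).
#' @return Tibble `partner_compartment`, `n_edges`, `fraction`; attribute
#'   `"fraction_endo_lyso_golgi"`.
#' @export
compartment_connectivity <- function(graph) {
  precedence <- c("endosome", "lysosome", "golgi", "mitochondria", "nucleus",
                  "other")
  resolve <- function(x) {
    if (is.na(x) || !nzchar(x)) return("other")
    parts <- trimws(strsplit(x, ",")[[1]])
    hit <- precedence[precedence %in% parts]
    if (length(hit)) hit[1] else "other"
  }
  comp <- vapply(igraph::V(graph)$compartment, resolve, character(1))
  names(comp) <- igraph::V(graph)$name
  el <- igraph::as_data_frame(graph, what = "edges")
  ca <- comp[el$from]; cb <- comp[el$to]
  endo_edge <- ca == "endosome" | cb == "endosome"
  partner <- ifelse(ca == "endosome", cb, ca)  # both endosomal -> endosome
  partner <- partner[endo_edge]
  tab <- table(factor(partner, levels = precedence))
  out <- tibble(partner_compartment = names(tab), n_edges = as.integer(tab),
                fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab) else 0)
  attr(out, "fraction_endo_lyso_golgi") <-
    sum(out$fraction[out$partner_compartment %in%
                       c("endosome", "lysosome", "golgi")])
  out
}
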