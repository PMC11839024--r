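#' Pipeline configuration with study-default thresholds
#'
#' Collects every tunable threshold of the pipeline with its default:
#' co-elution score floor 0.7 in 2 replicates, 25-protein / 67 kDa complex
#' filters, cross-link search score > 40, SPOC > 0.33, 35 A standard /
#' 30 A link-assisted distance ceilings, pLDDT > 70 confidence gate,
#' 2-residue variant window, 100 rewiring permutations, 10% target
#' false-positive rate. A config round-trips unchanged through YAML
#' (see [write_config()] / [read_config()]).
#'
#' @param ... Named overrides of any default.
#' @param seed Master seed for every stochastic step.
#' @param out_dir Optional output directory for [run_pipeline()] exports.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(..., seed = 1L, out_dir = NULL) {
  cfg <- list(
    bn_score_min = 0.7,
    bn_min_replicates = 2L,
    bn_max_complex_size = 25L,
    bn_min_peak_mass_kda = 67,
    xl_score_min = 40,
    spoc_min = 0.33,
    distance_threshold = 35,
    distance_threshold_assisted = 30,
    plddt_min = 70,
    trimer_interface_min = 0.5,
    variant_window = 2L,
    rewire_permutations = 100L,
    fp_target = 0.10,
    contact_cutoff = 8,
    seed = as.integer(seed),
    out_dir = out_dir
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param file Path for YAML serialization.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname pipeline_config
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipeline_config, c(raw[setdiff(names(raw), c("seed", "out_dir"))],
                             list(seed = raw$seed, out_dir = raw$out_dir)))
}

#' Run the full pipeline on a synthetic world
#'
#' Orchestrates every stage end to end on generated inputs with known
#' ground truth: meta-analysis scoring and proteome call, co-fractionation
#' scoring and filtering, cross-link dedup and pair collapse, network
#' integration with endosome centering, core component, statistics,
#' communities, rewiring nulls and 3-clique enumeration, structural
#' distance evaluation and prediction triage, and the variant-interface
#' scan. Deterministic given `config$seed`; the report contains every key
#' even when a count is zero.
#'
#' @param config A [pipeline_config()].
#' @param world Optional pre-built [synthetic_world()]; generated from
#'   `config$seed` when `NULL`.
#' @return List with `report` (nested tally list, JSON-serializable) and
#'   `objects` (the intermediate results for inspection).
#' @export
run_pipeline <- function(config = pipeline_config(), world = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  world <- world %||% synthetic_world(seed = seed)

  # --- meta-analysis --------------------------------------------------
  presence <- world$presence
  evidence <- dplyr::mutate(
    presence,
    is_reference = .data$label == "endosome",
    ip_abundance = .data$dataset_presence +
      with_substream(seed, "meta_abundance", rnorm(nrow(presence), sd = 1)),
    ref_interaction_count = with_substream(
      seed, "meta_interactions",
      stats::rpois(nrow(presence), lambda = ifelse(.data$label == "endosome", 4, 1)))
  )
  scored <- combine_scores(evidence)
  roc <- metric_roc(scored, .data$combined_score, .data$is_reference,
                    fp_max = config$fp_target)
  call <- call_endosomal(scored, fp_target = config$fp_target)
  meta_glance <- glance(call)

  # --- co-fractionation ----------------------------------------------
  cpx <- world$complexes
  pairs_within <- purrr::map_dfr(split(cpx$accession, cpx$complex_id),
                                 function(acc) {
    cmb <- utils::combn(sort(acc), 2)
    tibble(accession_a = cmb[1, ], accession_b = cmb[2, ])
  })
  bn_scores <- score_coelution_pairs(world$profiles, pairs_within)
  cpx_meta <- dplyr::mutate(
    dplyr::add_count(cpx, .data$complex_id, name = "complex_size"),
    accession_a = .data$accession)
  bn_cand <- dplyr::left_join(
    bn_scores,
    unique(cpx_meta[c("accession_a", "complex_id", "complex_size", "peak_fraction")]),
    by = "accession_a")
  bn_filtered <- filter_bn_candidates(
    bn_cand, calibration = bn_calibration(),
    score_min = config$bn_score_min, min_replicates = config$bn_min_replicates,
    max_complex_size = config$bn_max_complex_size,
    min_peak_mass_kda = config$bn_min_peak_mass_kda)
  bn_pass <- bn_filtered[bn_filtered$passes_filters, ]

  # --- cross-link table ----------------------------------------------
  links <- dedup_crosslinks(world$links, score_min = config$xl_score_min)
  xl_model_edges <- collapse_to_pairs(links)
  xl_hetero <- dplyr::bind_rows(
    xl_model_edges[!xl_model_edges$is_self,
                   c("accession_a", "accession_b", "xl_count")],
    world$xl_edges
  )

  # --- network ---------------------------------------------------------
  ann <- dplyr::mutate(world$proteins,
                       compartment = ifelse(.data$label == "endosome",
                                            "endosome", "other"))
  graph <- build_network(xl_hetero, bn_pass,
                         annotations = ann[c("accession", "compartment")])
  endo_set <- world$proteins$accession[world$proteins$label == "endosome"]
  centered <- endosome_center_filter(graph, endosomal = endo_set)
  core <- core_component(centered)
  stats_core <- network_stats(core)
  communities <- if (igraph::vcount(core) > 1) detect_communities(core) else
    tibble(accession = character(), community = integer())
  nulls <- if (igraph::ecount(core) >= 2) {
    rewire_null(core, n_permutations = config$rewire_permutations, seed = seed)
  } else {
    list()
  }
  coherence <- if (length(nulls)) {
    complex_coherence(core, world$complexes, nulls)
  } else {
    NULL
  }
  cliques <- enumerate_3cliques(graph)

  # --- structures ------------------------------------------------------
  evals <- evaluate_crosslinks(world$model, links,
                               threshold = config$distance_threshold,
                               plddt_min = config$plddt_min)
  eval_sum <- glance(evals)
  category <- classify_prediction(evals, spoc = 0.8,
                                  spoc_min = config$spoc_min)

  # --- variants --------------------------------------------------------
  scan <- variant_interface_scan(world$variants, world$contacts,
                                 window = config$variant_window)

  report <- list(
    seed = seed,
    meta = list(
      n_proteins = nrow(presence),
      n_reference = sum(evidence$is_reference),
      n_predicted = meta_glance$n_predicted,
      threshold = meta_glance$threshold,
      realized_fp_rate = meta_glance$realized_fp_rate,
      reference_recall = meta_glance$reference_recall,
      partial_auc = roc$pauc,
      partial_auc_normalized = roc$pauc_normalized
    ),
    bn = list(
      n_candidate_pairs = nrow(bn_filtered),
      n_passing_pairs = nrow(bn_pass)
    ),
    xl = list(
      n_unique_links = nrow(links),
      n_intra_links = sum(links$is_intra),
      n_inter_links = sum(!links$is_intra),
      n_interactions = nrow(xl_hetero)
    ),
    network = list(
      n_nodes = igraph::vcount(graph),
      n_edges = igraph::ecount(graph),
      n_nodes_centered = igraph::vcount(centered),
      n_edges_centered = igraph::ecount(centered),
      n_nodes_core = stats_core$n_nodes,
      n_edges_core = stats_core$n_edges,
      mean_shortest_path = stats_core$mean_shortest_path,
      powerlaw_r2 = stats_core$powerlaw_r2,
      n_communities = attr(communities, "n_communities") %||% 0L,
      n_3cliques = nrow(cliques),
      coherence_p_value = if (!is.null(coherence)) coherence$p_value else NA_real_
    ),
    structures = list(
      n_links_evaluated = eval_sum$n_links,
      n_within = eval_sum$n_within,
      n_exceeded = eval_sum$n_exceeded,
      n_unstructured = eval_sum$n_unstructured,
      n_unmapped = eval_sum$n_unmapped,
      frac_within = eval_sum$frac_within,
      frac_within_inter = eval_sum$frac_within_inter,
      category = category
    ),
    variants = list(
      n_variants = nrow(scan),
      n_near_interface = sum(scan$near_interface)
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(links, file.path(config$out_dir, "unique_links.tsv"))
    readr::write_tsv(as_tibble(igraph::as_data_frame(graph, "edges")),
                     file.path(config$out_dir, "edges.tsv"))
    readr::write_tsv(scan, file.path(config$out_dir, "variant_scan.tsv"))
  }

  list(report = report,
       objects = list(world = world, call = call, roc = roc,
                      bn_filtered = bn_filtered, links = links, graph = graph,
                      centered = centered, core = core, stats = stats_core,
                      communities = communities, coherence = coherence,
                      cliques = cliques, evaluations = evals, scan = scan))
}
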