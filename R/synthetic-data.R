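#' Simulate a multi-study presence/absence matrix with compartment labels
#'
#' Emulates a meta-analysis input: each protein carries a ground-truth
#' compartment label and is detected in each of `n_datasets` independent
#' studies with a label-specific sensitivity. Endosome-resident proteins
#' detected with higher sensitivity than background proteins produce the
#' dataset-presence signal the meta-analysis metrics exploit.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param n_datasets Number of independent studies (columns), >= 2.
#' @param sensitivity Named numeric vector of per-class detection
#'   probabilities in `[0, 1]`, e.g. `c(endosome = 0.5, other = 0.05)`.
#'   Names define the label classes.
#' @param class_prop Named numeric vector of class proportions (same names
#'   as `sensitivity`); normalized internally. Default: 20% endosomal.
#' @param seed Integer seed; the generator draws from its own named
#'   substream so results are reproducible and independent of other
#'   generators.
#'
#' @return A tibble with columns `accession`, `label`, and one 0/1 column
#'   per dataset (`ds_01`, `ds_02`, ...). `dataset_presence` holds the row
#'   sum.
#' @export
#' @examples
#' gen_presence_matrix(20, 4, c(endosome = 1, other = 0), seed = 1)
gen_presence_matrix <- function(n_proteins, n_datasets,
                                sensitivity = c(endosome = 0.5, other = 0.05),
                                class_prop = NULL, seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  n_datasets <- assert_count(n_datasets, "n_datasets", min = 2L)
  if (is.null(names(sensitivity)) || any(!nzchar(names(sensitivity)))) {
    abort("`sensitivity` must be a named vector of per-class probabilities")
  }
  if (any(sensitivity < 0 | sensitivity > 1)) {
    abort("`sensitivity` values must lie in [0, 1]")
  }
  classes <- names(sensitivity)
  if (is.null(class_prop)) {
    class_prop <- setNames(rep(1, length(classes)), classes)
    if ("endosome" %in% classes && length(classes) > 1L) {
      class_prop[] <- 0.8 / (length(classes) - 1L)
      class_prop["endosome"] <- 0.2
    }
  }
  class_prop <- class_prop[classes] / sum(class_prop[classes])

  # deterministic label assignment by proportion, then seeded detection draws
  counts <- floor(n_proteins * class_prop)
  rem <- n_proteins - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  labels <- rep(classes, counts)

  mat <- with_substream(seed, "presence_matrix", {
    p <- sensitivity[labels]
    matrix(as.integer(runif(n_proteins * n_datasets) < rep(p, n_datasets)),
           nrow = n_proteins, ncol = n_datasets)
  })
  colnames(mat) <- sprintf("ds_%02d", seq_len(n_datasets))
  out <- tibble(
    accession = sprintf("SP%05d", seq_len(n_proteins)),
    label = labels
  )
  out <- dplyr::bind_cols(out, as_tibble(mat))
  out$dataset_presence <- as.integer(rowSums(mat))
  out
}

#' Simulate Gaussian co-elution profiles for protein complexes
#'
#' Each complex elutes as a Gaussian peak centered on its assigned native-gel
#' fraction; all member proteins share that peak, so co-complex members have
#' correlated profiles while members of peaks elsewhere do not.
#' Multiplicative log-normal noise with coefficient of variation `noise_cv`
#' is applied per protein, replicate and fraction.
#'
#' @param complexes Tibble with columns `complex_id`, `accession`,
#'   `peak_fraction` (in `[1, n_fractions]`; fraction 1 = highest apparent
#'   mass).
#' @param n_fractions Number of gel fractions (default 48).
#' @param n_replicates Biological replicates (default 3).
#' @param peak_width Gaussian SD of the elution peak, in fractions.
#' @param noise_cv Coefficient of variation of multiplicative noise; 0 gives
#'   noise-free profiles.
#' @param amplitude Peak intensity scale.
#' @param seed Integer seed (named substream).
#'
#' @return Long tibble: `accession`, `replicate`, `fraction`, `intensity`.
#' @export
gen_elution_profiles <- function(complexes, n_fractions = 48L, n_replicates = 3L,
                                 peak_width = 2, noise_cv = 0.1,
                                 amplitude = 1e6, seed = 1L) {
  stopifnot(all(c("complex_id", "accession", "peak_fraction") %in% names(complexes)))
  n_fractions <- assert_count(n_fractions, "n_fractions", min = 2L)
  n_replicates <- assert_count(n_replicates, "n_replicates")
  if (any(complexes$peak_fraction < 1 | complexes$peak_fraction > n_fractions)) {
    abort(sprintf("`peak_fraction` must lie in [1, %d]", n_fractions))
  }

  grid <- tidyr::expand_grid(
    complexes[c("accession", "peak_fraction")],
    replicate = seq_len(n_replicates),
    fraction = seq_len(n_fractions)
  )
  mu <- amplitude * exp(-(grid$fraction - grid$peak_fraction)^2 / (2 * peak_width^2))
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_substream(seed, "elution_profiles",
                   exp(rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog)))
  } else {
    rep(1, nrow(grid))
  }
  tibble(
    accession = grid$accession,
    replicate = grid$replicate,
    fraction = grid$fraction,
    intensity = mu * noise
  )
}

#' Generate a synthetic multi-chain structural model
#'
#' Builds Calpha-only chains either as ideal alpha-helices (rise 1.5 A,
#' 100 degrees per residue, radius 2.3 A, giving consecutive Calpha-Calpha
#' distances of ~3.8 A) or as fixed-step random walks. Chains are offset
#' laterally by `chain_spacing` so inter-chain contacts are controllable.
#' Per-residue confidence (pLDDT scale) is attached.
#'
#' @param chain_lengths Integer vector of residues per chain (each >= 5).
#' @param fold `"helix-bundle"` or `"random-walk"`.
#' @param plddt Per-residue confidence: a single number, a vector recycled
#'   per chain, or a list of per-chain vectors. Default 90.
#' @param chain_spacing Lateral offset between consecutive chains, in A.
#' @param accessions Accession per chain (defaults to `SYNP01`, ...).
#' @param offsets Full-length sequence offset per chain (structure residue 1
#'   corresponds to full-length position `offset + 1`). Default 0.
#' @param seed Integer seed (named substream; used by the random walk).
#'
#' @return A `structure_model`: list with `atoms` (tibble `chain`, `resno`,
#'   `x`, `y`, `z`, `plddt`), `chain_map` (tibble `chain`, `accession`,
#'   `offset`), `source`, `model_id`.
#' @export
gen_structure <- function(chain_lengths, fold = c("helix-bundle", "random-walk"),
                          plddt = 90, chain_spacing = 10,
                          accessions = NULL, offsets = NULL, seed = 1L) {
  fold <- match.arg(fold)
  if (any(chain_lengths < 5)) abort("every chain must have >= 5 residues")
  n_chain <- length(chain_lengths)
  chains <- LETTERS[seq_len(n_chain)]
  accessions <- accessions %||% sprintf("SYNP%02d", seq_len(n_chain))
  offsets <- offsets %||% rep(0L, n_chain)

  plddt_list <- if (is.list(plddt)) {
    plddt
  } else {
    lapply(chain_lengths, function(n) rep_len(plddt, n))
  }

  coords <- with_substream(seed, "structure", {
    purrr::map(seq_len(n_chain), function(k) {
      n <- chain_lengths[k]
      if (fold == "helix-bundle") {
        theta <- (seq_len(n) - 1) * 100 * pi / 180
        cbind(x = 2.3 * cos(theta) + (k - 1) * chain_spacing,
              y = 2.3 * sin(theta),
              z = 1.5 * (seq_len(n) - 1))
      } else {
        steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
        steps <- 3.8 * steps / sqrt(rowSums(steps^2))
        xyz <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
        xyz[, 1] <- xyz[, 1] + (k - 1) * chain_spacing
        colnames(xyz) <- c("x", "y", "z")
        xyz
      }
    })
  })

  # coordinates held at PDB precision (0.001 A) so files round-trip exactly
  atoms <- purrr::map2_dfr(seq_len(n_chain), coords, function(k, xyz) {
    tibble(chain = chains[k], resno = seq_len(chain_lengths[k]),
           x = round(xyz[, "x"], 3), y = round(xyz[, "y"], 3),
           z = round(xyz[, "z"], 3),
           plddt = plddt_list[[k]][seq_len(chain_lengths[k])])
  })
  chain_map <- tibble(chain = chains, accession = accessions,
                      offset = as.integer(offsets))
  structure_model(atoms, chain_map, source = "synthetic",
                  model_id = sprintf("synth_%s", paste(chain_lengths, collapse = "x")))
}

#' Plant cross-links on a structural model
#'
#' Draws `n_true` residue-pair links from pairs whose Calpha-Calpha distance
#' is at most `true_max_dist`, and `n_decoy` links uniformly from the
#' remaining (longer) pairs, all without replacement. Each link carries a
#' ground-truth `is_true_contact` flag, so downstream distance evaluation can
#' be checked exactly against the planted fraction.
#'
#' @param model A `structure_model`.
#' @param n_true,n_decoy Numbers of satisfiable and decoy links requested.
#'   If a pool is smaller than requested, all of it is used and the
#'   shortfall is reported via a message and the `shortfall` attribute.
#' @param true_max_dist Distance ceiling (A) defining satisfiable pairs.
#' @param chemistry Linker chemistry label attached to every link.
#' @param min_seq_sep Minimum sequence separation for intra-chain pairs
#'   (avoids trivially-near backbone neighbours).
#' @param inter_only If `TRUE`, only inter-chain pairs are eligible.
#' @param seed Integer seed (named substream).
#'
#' @return Tibble of links in canonical order: `accession_a`, `pos_a`,
#'   `accession_b`, `pos_b` (1-based full-length positions), `chemistry`,
#'   `score`, `replicate`, `is_true_contact`.
#' @export
gen_crosslinks <- function(model, n_true, n_decoy, true_max_dist = 35,
                           chemistry = "DSSO", min_seq_sep = 5L,
                           inter_only = FALSE, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  n_true <- assert_count(n_true, "n_true", min = 0L)
  n_decoy <- assert_count(n_decoy, "n_decoy", min = 0L)
  res <- model_positions(model)
  if (any(table(res$chain) < 2)) abort("model needs >= 2 residues per chain")

  idx <- utils::combn(nrow(res), 2)
  a <- idx[1, ]; b <- idx[2, ]
  keep <- res$chain[a] != res$chain[b] |
    abs(res$resno[a] - res$resno[b]) >= min_seq_sep
  if (inter_only) keep <- keep & res$chain[a] != res$chain[b]
  a <- a[keep]; b <- b[keep]
  d <- sqrt((res$x[a] - res$x[b])^2 + (res$y[a] - res$y[b])^2 +
              (res$z[a] - res$z[b])^2)

  pool <- tibble(
    accession_a = res$accession[a], pos_a = res$position[a],
    accession_b = res$accession[b], pos_b = res$position[b],
    distance = d, is_true_contact = d <= true_max_dist
  )
  true_pool <- which(pool$is_true_contact)
  decoy_pool <- which(!pool$is_true_contact)

  shortfall <- c(true = max(0L, n_true - length(true_pool)),
                 decoy = max(0L, n_decoy - length(decoy_pool)))
  if (any(shortfall > 0)) {
    inform(sprintf(
      "eligible pool smaller than requested: %d true and %d decoy links short",
      shortfall[["true"]], shortfall[["decoy"]]))
  }

  links <- with_substream(seed, "crosslinks", {
    pick_true <- sample(true_pool, min(n_true, length(true_pool)))
    pick_decoy <- sample(decoy_pool, min(n_decoy, length(decoy_pool)))
    picked <- pool[c(pick_true, pick_decoy), ]
    picked$score <- runif(nrow(picked), 45, 150)
    picked
  })
  links$chemistry <- chemistry
  links$replicate <- 1L
  links$distance <- NULL
  links <- canonicalize_pairs(links, pa = "pos_a", pb = "pos_b")
  links <- dplyr::arrange(links, .data$accession_a, .data$pos_a,
                          .data$accession_b, .data$pos_b)
  attr(links, "shortfall") <- shortfall
  links
}

#' Plant near- and far-interface variants
#'
#' Places `n_near` variants within `window` residues of some interface
#' contact position and `n_far` variants strictly farther than `window` from
#' every contact on the same protein, attaching the ground-truth label so
#' the interface scan can be validated exactly.
#'
#' @param model A `structure_model` (supplies per-accession sequence extents).
#' @param contacts Tibble of interface contacts: `accession`, `position`
#'   (1-based full-length). Must be non-empty when `n_near > 0`.
#' @param n_near,n_far Numbers of variants per class.
#' @param window Sequence window (residues) defining "near".
#' @param seed Integer seed (named substream).
#'
#' @return Tibble: `accession`, `position`, `ref`, `alt`, `annotation`,
#'   `truth_near`.
#' @export
gen_variants <- function(model, contacts, n_near, n_far, window = 2L, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  n_near <- assert_count(n_near, "n_near", min = 0L)
  n_far <- assert_count(n_far, "n_far", min = 0L)
  if (n_near > 0 && (is.null(contacts) || nrow(contacts) == 0)) {
    abort("`contacts` must be non-empty when n_near > 0")
  }
  res <- model_positions(model)
  extents <- dplyr::summarise(dplyr::group_by(res, .data$accession),
                              len = max(.data$position), .groups = "drop")

  near_ok <- far_ok <- tibble(accession = character(), position = integer())
  for (i in seq_len(nrow(extents))) {
    acc <- extents$accession[i]
    len <- extents$len[i]
    cpos <- contacts$position[contacts$accession == acc]
    all_pos <- seq_len(len)
    if (length(cpos)) {
      is_near <- vapply(all_pos, function(p) min(abs(p - cpos)) <= window,
                        logical(1))
    } else {
      is_near <- rep(FALSE, len)
    }
    near_ok <- dplyr::bind_rows(near_ok,
      tibble(accession = acc, position = all_pos[is_near]))
    far_ok <- dplyr::bind_rows(far_ok,
      tibble(accession = acc, position = all_pos[!is_near]))
  }
  if (n_near > nrow(near_ok) || n_far > nrow(far_ok)) {
    abort(sprintf("impossible placement: %d near / %d far positions available",
                  nrow(near_ok), nrow(far_ok)))
  }

  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  with_substream(seed, "variants", {
    picked <- dplyr::bind_rows(
      dplyr::mutate(near_ok[sample(nrow(near_ok), n_near), ], truth_near = TRUE),
      dplyr::mutate(far_ok[sample(nrow(far_ok), n_far), ], truth_near = FALSE)
    )
    picked$ref <- sample(aa, nrow(picked), replace = TRUE)
    picked$alt <- sample(aa, nrow(picked), replace = TRUE)
    picked$annotation <- "synthetic candidate disease variant"
    picked[c("accession", "position", "ref", "alt", "annotation", "truth_near")]
  })
}

#' Generate a complete synthetic study world
#'
#' Bundles every input the pipeline consumes -- labelled proteins with a
#' multi-study presence matrix, complexes with co-elution profiles,
#' structural models with planted cross-links and variants -- with ground
#' truth attached throughout. Regeneration with the same seed is
#' bit-identical.
#'
#' @param n_proteins Proteins in the presence matrix.
#' @param n_datasets Studies in the presence matrix.
#' @param n_complexes Number of co-elution complexes.
#' @param complex_size Members per complex.
#' @param noise_cv Elution noise level.
#' @param sensitivity Per-class detection sensitivity (see
#'   [gen_presence_matrix()]).
#' @param seed Integer master seed; each generator draws from its own
#'   substream.
#'
#' @return List with elements `proteins`, `presence`, `complexes`,
#'   `profiles`, `model`, `links`, `contacts`, `variants`, `seed`.
#' @export
synthetic_world <- function(n_proteins = 400L, n_datasets = 16L,
                            n_complexes = 8L, complex_size = 4L,
                            noise_cv = 0.1,
                            sensitivity = c(endosome = 0.5, other = 0.05),
                            seed = 1L) {
  presence <- gen_presence_matrix(n_proteins, n_datasets, sensitivity, seed = seed)

  endo_acc <- presence$accession[presence$label == "endosome"]
  other_acc <- presence$accession[presence$label != "endosome"]
  members <- head(c(endo_acc, other_acc), n_complexes * complex_size)
  peaks <- with_substream(seed, "complex_peaks",
                          sample(seq(4L, 30L, by = 2L), n_complexes))
  complexes <- tibble(
    complex_id = rep(sprintf("CPX%02d", seq_len(n_complexes)), each = complex_size),
    accession = members,
    peak_fraction = rep(peaks, each = complex_size)
  )
  profiles <- gen_elution_profiles(complexes, noise_cv = noise_cv, seed = seed)

  # collapsed protein-pair cross-link evidence across the wider proteome:
  # preferential attachment gives the hub-rich, power-law degree structure
  # of a real organelle interactome; endosomal accessions come first, so
  # hubs are endosome-enriched
  n_net <- min(150L, n_proteins)
  net_acc <- presence$accession[seq_len(n_net)]
  xl_edges <- with_substream(seed, "xl_network", {
    g <- igraph::sample_pa(n_net, m = 2, directed = FALSE)
    el <- igraph::as_edgelist(g)
    tibble(accession_a = net_acc[el[, 1]], accession_b = net_acc[el[, 2]],
           xl_count = sample(1:4, nrow(el), replace = TRUE,
                             prob = c(0.6, 0.2, 0.1, 0.1)))
  })
  xl_edges <- canonicalize_pairs(xl_edges)
  xl_edges <- dplyr::distinct(xl_edges, .data$accession_a, .data$accession_b,
                              .keep_all = TRUE)

  # short second chain keeps the interface local, so far-from-interface
  # positions exist on chain A for the variant scan
  model <- gen_structure(c(120L, 20L), fold = "helix-bundle", chain_spacing = 8,
                         accessions = head(endo_acc, 2L), seed = seed)
  links <- gen_crosslinks(model, n_true = 30L, n_decoy = 10L, seed = seed)
  contacts <- contact_residues(model, "A", "B", cutoff = 8)
  variants <- gen_variants(model, contacts, n_near = 3L, n_far = 3L, seed = seed)

  list(proteins = presence[c("accession", "label")], presence = presence,
       complexes = complexes, profiles = profiles, xl_edges = xl_edges,
       model = model, links = links, contacts = contacts, variants = variants,
       seed = seed)
}
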