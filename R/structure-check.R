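#' Calpha-Calpha distance between two residues of a model
#'
#' @param model A `structure_model`.
#' @param accession_a,pos_a,accession_b,pos_b Residue references in 1-based
#'   full-length coordinates (vectorized).
#' @return Numeric distances in A; `NA` where a residue is outside the
#'   modeled range or lacks coordinates.
#' @export
ca_distance <- function(model, accession_a, pos_a, accession_b, pos_b) {
  res <- model_positions(model)
  key <- paste(res$accession, res$position)
  ia <- match(paste(accession_a, pos_a), key)
  ib <- match(paste(accession_b, pos_b), key)
  sqrt((res$x[ia] - res$x[ib])^2 + (res$y[ia] - res$y[ib])^2 +
         (res$z[ia] - res$z[ib])^2)
}

#' Evaluate cross-links against a model's distance constraints
#'
#' Maps each cross-link onto the model and classifies it: `within` if both
#' residues are modeled, both pass the confidence gate (pLDDT strictly
#' greater than `plddt_min`), and the Calpha-Calpha distance is at most
#' `threshold`; `exceeded` if gated and mapped but longer; `unstructured`
#' if mapped but either residue fails the confidence gate; `unmapped` if a
#' residue lies outside the modeled range. Experimental structures carry no
#' pLDDT (`NA`) and skip the gate. The summary fraction-within is computed
#' over `within` plus `exceeded` links only, separately for intra- and
#' inter-protein links.
#'
#' The default 35 A ceiling is the DSSO/DMTMM constraint used for standard
#' predictions and PDB structures; link-assisted predictions use the
#' stricter 30 A (see [distance_threshold()]).
#'
#' @param model A `structure_model`.
#' @param links Tibble with `accession_a`, `pos_a`, `accession_b`, `pos_b`
#'   (full-length coordinates); other columns are carried through.
#' @param threshold Distance ceiling in A.
#' @param plddt_min Confidence gate; residues with pLDDT `<= plddt_min` are
#'   unstructured. Set `gate_plddt = FALSE` to disable.
#' @param gate_plddt Whether to apply the confidence gate.
#' @return An `xl_evaluation`: the per-link tibble with `distance`,
#'   `status`, `min_plddt`, `threshold_used`, plus chain/residue addresses
#'   for visualization. `glance()` gives the summary fractions.
#' @export
evaluate_crosslinks <- function(model, links, threshold = 35, plddt_min = 70,
                                gate_plddt = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  res <- model_positions(model)
  key <- paste(res$accession, res$position)
  ia <- match(paste(links$accession_a, links$pos_a), key)
  ib <- match(paste(links$accession_b, links$pos_b), key)

  out <- as_tibble(links)
  out$chain_a <- res$chain[ia]
  out$resno_a <- res$resno[ia]
  out$chain_b <- res$chain[ib]
  out$resno_b <- res$resno[ib]
  out$distance <- sqrt((res$x[ia] - res$x[ib])^2 + (res$y[ia] - res$y[ib])^2 +
                         (res$z[ia] - res$z[ib])^2)
  pl_a <- res$plddt[ia]
  pl_b <- res$plddt[ib]
  out$min_plddt <- pmin(pl_a, pl_b)

  unmapped <- is.na(ia) | is.na(ib) | is.na(out$distance)
  gated_out <- !unmapped & gate_plddt &
    ((!is.na(pl_a) & pl_a <= plddt_min) | (!is.na(pl_b) & pl_b <= plddt_min))
  out$status <- dplyr::case_when(
    unmapped ~ "unmapped",
    gated_out ~ "unstructured",
    out$distance <= threshold ~ "within",
    TRUE ~ "exceeded"
  )
  out$threshold_used <- threshold
  out$is_intra <- out$accession_a == out$accession_b

  class(out) <- c("xl_evaluation", class(out))
  attr(out, "plddt_min") <- plddt_min
  out
}

#' @exportS3Method generics::glance
glance.xl_evaluation <- function(x, ...) {
  frac_within <- function(df) {
    n_ok <- sum(df$status == "within")
    n_eval <- sum(df$status %in% c("within", "exceeded"))
    if (n_eval == 0) NA_real_ else n_ok / n_eval
  }
  tibble(
    n_links = nrow(x),
    n_within = sum(x$status == "within"),
    n_exceeded = sum(x$status == "exceeded"),
    n_unstructured = sum(x$status == "unstructured"),
    n_unmapped = sum(x$status == "unmapped"),
    frac_within = frac_within(x),
    frac_within_intra = frac_within(x[x$is_intra, ]),
    frac_within_inter = frac_within(x[!x$is_intra, ]),
    threshold = x$threshold_used[1] %||% NA_real_
  )
}

#' Distance ceiling for a chemistry / model-source combination
#'
#' Standard predictions and PDB structures use 35 A for every chemistry;
#' link-assisted predictions use the stricter 30 A for all cross-linkers
#' (the links already informed the model).
#'
#' @param chemistry `"DSSO"`, `"DHSO"` or `"DMTMM"`.
#' @param source Model source (see [structure_model()]).
#' @param overrides Optional named vector `"chemistry:source" = value`.
#' @return Distance threshold in A.
#' @export
distance_threshold <- function(chemistry = "DSSO",
                               source = "pairwise-prediction",
                               overrides = NULL) {
  key <- paste(chemistry, source, sep = ":")
  if (!is.null(overrides) && key %in% names(overrides)) {
    return(unname(overrides[key]))
  }
  if (source == "link-assisted-prediction") 30 else 35
}

#' Triage a structural prediction by score and cross-link agreement
#'
#' A record is `low-confidence` when its classifier score does not exceed
#' `spoc_min`; otherwise `supported` when more than `majority` of the
#' distance-evaluable interprotein links are within range, `unstructured-only`
#' when every interprotein link falls in unstructured or unmapped regions,
#' and `violated` otherwise. Records missing a SPOC score fall back to
#' ipTM only when an explicit `iptm_min` is supplied; otherwise they are
#' flagged `unscored`.
#'
#' @param evaluations An `xl_evaluation` (or compatible tibble with
#'   `status` and `is_intra`).
#' @param spoc SPOC classifier score in `[0, 1]` (`NA` if unscored).
#' @param iptm Optional ipTM fallback score.
#' @param spoc_min Score floor (strict `>`), default 0.33.
#' @param majority Fraction of within-range links required (strict `>`),
#'   default 0.5.
#' @param iptm_min Optional ipTM floor enabling the fallback.
#' @return One of `"supported"`, `"unstructured-only"`, `"violated"`,
#'   `"low-confidence"`, `"unscored"`; `NA` (with a warning) for a record
#'   with no interprotein links.
#' @export
classify_prediction <- function(evaluations, spoc, iptm = NA_real_,
                                spoc_min = 0.33, majority = 0.5,
                                iptm_min = NULL) {
  if (is.na(spoc)) {
    if (is.null(iptm_min) || is.na(iptm)) return("unscored")
    if (iptm <= iptm_min) return("low-confidence")
  } else if (spoc <= spoc_min) {
    return("low-confidence")
  }
  ev <- evaluations[!evaluations$is_intra, , drop = FALSE]
  if (nrow(ev) == 0) {
    warn("record has no interprotein links; returning NA category")
    return(NA_character_)
  }
  n_within <- sum(ev$status == "within")
  n_eval <- sum(ev$status %in% c("within", "exceeded"))
  if (n_eval == 0) return("unstructured-only")
  if (n_within / n_eval > majority) "supported" else "violated"
}

#' Accept or reject a trimer prediction by interface quality
#'
#' A three-protein model is accepted when at least two of its three pairwise
#' interfaces have an interface-average score strictly greater than 0.5.
#' Missing interfaces count as 0.
#'
#' @param interface_scores Numeric vector of up to 3 per-interface average
#'   scores.
#' @param score_min Per-interface floor (strict `>`), default 0.5.
#' @param n_required Interfaces required above the floor, default 2.
#' @return Logical.
#' @export
trimer_quality <- function(interface_scores, score_min = 0.5, n_required = 2L) {
  scores <- rep(0, 3)
  scores[seq_along(interface_scores)] <- ifelse(is.na(interface_scores), 0,
                                                interface_scores)
  sum(scores > score_min) >= n_required
}

#' Interface contact residues between two chains
#'
#' Positions whose Calpha lies within `cutoff` of any Calpha on the partner
#' chain, reported in 1-based full-length coordinates.
#'
#' @param model A `structure_model`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Calpha-Calpha contact distance in A (default 8).
#' @return Tibble: `chain`, `accession`, `position`.
#' @export
contact_residues <- function(model, chain_a, chain_b, cutoff = 8) {
  res <- model_positions(model)
  ra <- res[res$chain == chain_a, ]
  rb <- res[res$chain == chain_b, ]
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    abort("both chains must be present in the model")
  }
  dmat <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)), function(i, j) {
    sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 + (ra$z[i] - rb$z[j])^2)
  })
  hit_a <- apply(dmat, 1, min) <= cutoff
  hit_b <- apply(dmat, 2, min) <= cutoff
  dplyr::bind_rows(
    ra[hit_a, c("chain", "accession", "position")],
    rb[hit_b, c("chain", "accession", "position")]
  )
}

#' Scan variants against predicted interface contacts
#'
#' A variant hits an interface when some contact residue on the same
#' protein lies within `window` positions of it in sequence (spatial
#' distance is not used). The nearest contact and its sequence gap are
#' reported.
#'
#' @param variants Tibble: `accession`, `position` (1-based full-length);
#'   other columns carried through.
#' @param contacts Tibble: `accession`, `position` of interface residues.
#' @param window Sequence window in residues (default 2).
#' @param sequence_lengths Optional named vector of protein lengths; variants
#'   beyond their sequence are flagged `out_of_range`.
#' @return Tibble: input plus `near_interface`, `nearest_contact`, `gap`
#'   (and `out_of_range` when lengths are supplied).
#' @export
variant_interface_scan <- function(variants, contacts, window = 2L,
                                   sequence_lengths = NULL) {
  out <- as_tibble(variants)
  nearest <- purrr::map(seq_len(nrow(out)), function(i) {
    cpos <- contacts$position[contacts$accession == out$accession[i]]
    if (length(cpos) == 0) return(c(NA_integer_, NA_integer_))
    gaps <- abs(cpos - out$position[i])
    j <- which.min(gaps)
    c(cpos[j], gaps[j])
  })
  out$nearest_contact <- vapply(nearest, `[`, numeric(1), 1)
  out$gap <- vapply(nearest, `[`, numeric(1), 2)
  out$near_interface <- !is.na(out$gap) & out$gap <= window
  if (!is.null(sequence_lengths)) {
    len <- unname(sequence_lengths[out$accession])
    out$out_of_range <- !is.na(len) & out$position > len
    if (any(out$out_of_range)) {
      warn(sprintf("%d variant(s) beyond sequence length", sum(out$out_of_range)))
    }
  }
  out
}

#' Export cross-link evaluations as a pseudobond file
#'
#' One line per mapped link in the `/CHAIN:RES@CA /CHAIN:RES@CA color`
#' format used by molecular viewers, colored by distance status. Unmapped
#' links are skipped and counted in the header comment. Ordering is
#' deterministic (canonical link order).
#'
#' @param evaluations An `xl_evaluation` (must carry chain/residue
#'   addresses, i.e. come from [evaluate_crosslinks()]).
#' @param file Output path.
#' @param colors Named vector mapping status to a color string.
#' @return The lines written, invisibly.
#' @export
export_pseudobonds <- function(evaluations, file,
                               colors = c(within = "#00b7c2",
                                          exceeded = "#d7263d",
                                          unstructured = "#f4a261")) {
  ev <- evaluations[order(evaluations$chain_a, evaluations$resno_a,
                          evaluations$chain_b, evaluations$resno_b), ]
  skipped <- sum(ev$status == "unmapped")
  ev <- ev[ev$status != "unmapped", ]
  lines <- c(
    sprintf("; pseudobonds: %d links, %d unmapped skipped", nrow(ev), skipped),
    sprintf("/%s:%d@CA /%s:%d@CA %s",
            ev$chain_a, ev$resno_a, ev$chain_b, ev$resno_b,
            unname(colors[ev$status]))
  )
  writeLines(lines, file)
  invisible(lines)
}
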