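#' Deduplicate and score-filter raw cross-link rows
#'
#' Canonicalizes each residue-pair link (`accession_a <= accession_b`; for
#' intra-protein links `pos_a <= pos_b`), removes rows at or below the
#' search-score floor (strictly greater than `score_min` is required, the
#' convention of the upstream search engine), rejects malformed positions
#' with a message, and collapses duplicates to one row per canonical
#' `(a, pos_a, b, pos_b, chemistry)` keeping the best score and counting
#' distinct replicates. Output order is canonical, so the result is
#' invariant to input row order and the operation is idempotent.
#'
#' @param links Tibble with `accession_a`, `pos_a`, `accession_b`, `pos_b`,
#'   `chemistry`, `score`, `replicate`.
#' @param score_min Strict score floor (default 40; a score of exactly 40
#'   is removed).
#' @return Unique-link tibble with `score` (best), `n_replicates`,
#'   `is_intra`; ground-truth columns (`is_true_contact`) are carried
#'   through with `any()`.
#' @export
dedup_crosslinks <- function(links, score_min = 40) {
  x <- as_tibble(links)
  bad <- !is.finite(x$pos_a) | !is.finite(x$pos_b) | x$pos_a < 1 | x$pos_b < 1 |
    x$pos_a != floor(x$pos_a) | x$pos_b != floor(x$pos_b)
  if (any(bad)) {
    inform(sprintf("rejected %d row(s) with malformed positions", sum(bad)))
    x <- x[!bad, ]
  }
  x <- x[x$score > score_min, ]
  if (nrow(x) == 0) {
    out <- x[c("accession_a", "pos_a", "accession_b", "pos_b", "chemistry",
               "score")]
    out$n_replicates <- integer(0)
    if ("is_true_contact" %in% names(x)) out$is_true_contact <- logical(0)
    out$is_intra <- logical(0)
    return(as_tibble(out))
  }
  x <- canonicalize_pairs(x, pa = "pos_a", pb = "pos_b")
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$accession_a, .data$pos_a, .data$accession_b,
                    .data$pos_b, .data$chemistry),
    score = max(.data$score),
    n_replicates = dplyr::n_distinct(.data$replicate),
    dplyr::across(dplyr::any_of("is_true_contact"), any),
    .groups = "drop"
  )
  out$is_intra <- out$accession_a == out$accession_b
  dplyr::arrange(out, .data$accession_a, .data$pos_a, .data$accession_b,
                 .data$pos_b, .data$chemistry)
}

#' Check cross-links against membrane-topology annotations
#'
#' Each residue is classed by the annotated segment containing it
#' (`cytosolic` vs non-cytosolic, with `lumenal` and `extracellular`
#' grouped); a residue inside a transmembrane segment takes the class of
#' the nearest flanking non-TM segment (linker-accessible lysines sit at TM
#' borders) and is flagged. A link is `consistent` when both residues fall
#' on the same side, `inconsistent` otherwise, and `unannotated` when
#' either residue is in no segment; unannotated links are excluded from the
#' consistent fraction.
#'
#' @param links Unique-link tibble (see [dedup_crosslinks()]).
#' @param topology Tibble `accession`, `start`, `end`, `class` with class
#'   in `cytosolic`, `lumenal`, `extracellular`, `TM`; segments
#'   non-overlapping within a protein, 1-based inclusive.
#' @return `links` with `side_a`, `side_b`, `tm_adjusted_a`,
#'   `tm_adjusted_b`, `verdict`; attribute `"consistent_fraction"` holds
#'   consistent / (consistent + inconsistent).
#' @export
topology_check <- function(links, topology) {
  side_of <- function(acc, pos) {
    seg <- topology[topology$accession == acc &
                      topology$start <= pos & topology$end >= pos, ]
    if (nrow(seg) == 0) return(c(NA_character_, "FALSE"))
    cls <- seg$class[1]
    if (cls == "TM") {
      flank <- topology[topology$accession == acc & topology$class != "TM", ]
      if (nrow(flank) == 0) return(c(NA_character_, "TRUE"))
      gap <- pmin(abs(flank$start - pos), abs(flank$end - pos))
      cls <- flank$class[which.min(gap)]
      return(c(cls, "TRUE"))
    }
    c(cls, "FALSE")
  }
  out <- as_tibble(links)
  sa <- t(mapply(side_of, out$accession_a, out$pos_a))
  sb <- t(mapply(side_of, out$accession_b, out$pos_b))
  grp <- function(cls) ifelse(is.na(cls), NA_character_,
                              ifelse(cls == "cytosolic", "cytosolic", "non-cytosolic"))
  out$side_a <- grp(sa[, 1])
  out$side_b <- grp(sb[, 1])
  out$tm_adjusted_a <- sa[, 2] == "TRUE"
  out$tm_adjusted_b <- sb[, 2] == "TRUE"
  out$verdict <- dplyr::case_when(
    is.na(out$side_a) | is.na(out$side_b) ~ "unannotated",
    out$side_a == out$side_b ~ "consistent",
    TRUE ~ "inconsistent"
  )
  n_cons <- sum(out$verdict == "consistent")
  n_eval <- sum(out$verdict %in% c("consistent", "inconsistent"))
  attr(out, "consistent_fraction") <- if (n_eval > 0) n_cons / n_eval else NA_real_
  out
}

#' Collapse residue-level links to protein-pair interaction edges
#'
#' One edge per unordered protein pair; `xl_count` counts the unique
#' residue-pair links supporting it. Inter-protein links define hetero
#' edges; intra-protein links are recorded as self rows (`is_self = TRUE`)
#' and never create hetero edges. Edge sets are additive: collapsing the
#' union of two disjoint link sets gives the union of edges with summed
#' counts.
#'
#' @param links Deduplicated unique-link tibble.
#' @return Edge tibble `accession_a`, `accession_b`, `xl_count`, `is_self`
#'   in canonical order.
#' @export
collapse_to_pairs <- function(links) {
  x <- canonicalize_pairs(as_tibble(links))
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$accession_a, .data$accession_b),
    xl_count = dplyr::n(),
    .groups = "drop"
  )
  out$is_self <- out$accession_a == out$accession_b
  dplyr::arrange(out, .data$accession_a, .data$accession_b)
}

#' Map secondary-chemistry links onto the primary interaction set
#'
#' Cross-links from secondary chemistries (acid-acid, acid-Lys) are mapped
#' onto the protein interactions defined by the primary (Lys-Lys) set.
#' Because shared peptide sequences make protein assignment ambiguous, each
#' secondary link's accessions are first expanded through the supplied
#' ambiguity groups, and the link annotates *every* primary pair covered by
#' the expansion -- one link may annotate multiple interactions. An empty
#' ambiguity table means exact accession matching.
#'
#' @param secondary Tibble of secondary-chemistry links (`accession_a`,
#'   `accession_b`, other columns carried through).
#' @param primary_pairs Tibble of primary protein pairs (`accession_a`,
#'   `accession_b`).
#' @param ambiguity Optional tibble `accession`, `group`: accessions
#'   sharing a group are interchangeable.
#' @return Tibble: one row per (secondary link x matched primary pair),
#'   with `matched_a`/`matched_b` naming the primary pair; unmatched links
#'   appear once with `NA` matches and `matched = FALSE`.
#' @export
map_secondary_chemistry <- function(secondary, primary_pairs, ambiguity = NULL) {
  prim <- canonicalize_pairs(as_tibble(primary_pairs))
  prim_key <- unique(paste(prim$accession_a, prim$accession_b))
  expand <- function(acc) {
    if (is.null(ambiguity) || nrow(ambiguity) == 0) return(acc)
    grps <- ambiguity$group[ambiguity$accession == acc]
    if (length(grps) == 0) return(acc)
    unique(c(acc, ambiguity$accession[ambiguity$group %in% grps]))
  }
  sec <- as_tibble(secondary)
  purrr::map_dfr(seq_len(nrow(sec)), function(i) {
    row <- sec[i, ]
    ea <- expand(row$accession_a)
    eb <- expand(row$accession_b)
    cand <- tidyr::expand_grid(ma = ea, mb = eb)
    cand <- canonicalize_pairs(cand, a = "ma", b = "mb")
    cand <- unique(cand)
    hits <- cand[paste(cand$ma, cand$mb) %in% prim_key, ]
    if (nrow(hits) == 0) {
      return(dplyr::mutate(row, matched_a = NA_character_,
                           matched_b = NA_character_, matched = FALSE))
    }
    dplyr::mutate(row[rep(1, nrow(hits)), ],
                  matched_a = hits$ma, matched_b = hits$mb, matched = TRUE)
  })
}
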