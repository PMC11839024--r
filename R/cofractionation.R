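#' Normalize a single elution profile
#'
#' @param x Non-negative intensity vector over fractions.
#' @param mode `"sum"` (values sum to 1) or `"max"` (maximum is 1). Zeros
#'   are preserved; normalization is idempotent.
#' @return Normalized vector; all-`NA` with a warning for an all-zero
#'   profile (degenerate profiles are excluded from correlation).
#' @export
normalize_profile <- function(x, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (all(x == 0, na.rm = TRUE)) {
    warn("all-zero profile; flagged as degenerate")
    return(rep(NA_real_, length(x)))
  }
  denom <- if (mode == "sum") sum(x, na.rm = TRUE) else max(x, na.rm = TRUE)
  x / denom
}

#' Normalize elution profiles per protein and replicate
#'
#' @param profiles Long tibble: `accession`, `replicate`, `fraction`,
#'   `intensity`.
#' @inheritParams normalize_profile
#' @return Same shape with normalized `intensity` and a logical `degenerate`
#'   column flagging all-zero profiles (their intensities become `NA`).
#' @export
normalize_profiles <- function(profiles, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  grp <- dplyr::group_by(as_tibble(profiles), .data$accession, .data$replicate)
  out <- dplyr::mutate(
    grp,
    degenerate = all(.data$intensity == 0, na.rm = TRUE),
    intensity = dplyr::if_else(
      rep(all(.data$intensity == 0, na.rm = TRUE), dplyr::n()),
      NA_real_,
      .data$intensity / (if (mode == "sum") sum(.data$intensity, na.rm = TRUE)
                         else max(.data$intensity, na.rm = TRUE))
    )
  )
  dplyr::ungroup(out)
}

#' Replicate-consensus elution profile with outlier handling
#'
#' Per protein, replicate profiles are normalized (sum mode), the
#' per-fraction median profile is formed, and the replicate most dissimilar
#' to it (lowest Pearson r) is dropped when its r falls below `r_floor`;
#' the mean of the surviving replicates is returned. With a single
#' replicate the profile passes through with a warning. `mode = "fraction"`
#' instead drops, within each replicate, the single fraction most deviant
#' from the median profile.
#'
#' @param profiles Long tibble: `accession`, `replicate`, `fraction`,
#'   `intensity`.
#' @param r_floor Correlation floor below which the most dissimilar
#'   replicate is dropped (default 0.5).
#' @param mode `"replicate"` (default) or `"fraction"` outlier handling.
#' @return Tibble `accession`, `fraction`, `intensity` (mean normalized
#'   profile); attribute `"dropped"` records dropped replicates and their r.
#' @export
consensus_profile <- function(profiles, r_floor = 0.5,
                              mode = c("replicate", "fraction")) {
  mode <- match.arg(mode)
  norm <- normalize_profiles(profiles, mode = "sum")
  norm <- norm[!norm$degenerate, ]
  dropped <- tibble(accession = character(), replicate = integer(), r = numeric())

  consensus_one <- function(df) {
    wide <- tidyr::pivot_wider(df[c("replicate", "fraction", "intensity")],
                               names_from = "replicate", values_from = "intensity")
    wide <- dplyr::arrange(wide, .data$fraction)
    mat <- as.matrix(wide[-1])
    if (ncol(mat) == 1) {
      warn(sprintf("single replicate for %s; consensus is the sole profile",
                   df$accession[1]))
      return(list(profile = tibble(fraction = wide$fraction, intensity = mat[, 1]),
                  dropped = NULL))
    }
    med <- apply(mat, 1, median)
    if (mode == "fraction") {
      # per replicate, null out the fraction most deviant from the median
      for (j in seq_len(ncol(mat))) {
        worst <- which.max(abs(mat[, j] - med))
        mat[worst, j] <- NA
      }
      return(list(profile = tibble(fraction = wide$fraction,
                                   intensity = rowMeans(mat, na.rm = TRUE)),
                  dropped = NULL))
    }
    rs <- apply(mat, 2, function(col) {
      if (stats::sd(col) == 0 || stats::sd(med) == 0) return(1)
      cor(col, med)
    })
    drop <- NULL
    if (min(rs) < r_floor && ncol(mat) >= 2) {
      j <- which.min(rs)
      drop <- tibble(accession = df$accession[1],
                     replicate = as.integer(colnames(mat)[j]), r = rs[j])
      mat <- mat[, -j, drop = FALSE]
    }
    list(profile = tibble(fraction = wide$fraction, intensity = rowMeans(mat)),
         dropped = drop)
  }

  pieces <- lapply(split(norm, norm$accession), consensus_one)
  out <- purrr::map_dfr(names(pieces), function(acc) {
    dplyr::mutate(pieces[[acc]]$profile, accession = acc, .before = 1)
  })
  dropped <- purrr::map_dfr(pieces, "dropped")
  attr(out, "dropped") <- dropped
  out
}

#' Pearson co-elution correlation for protein pairs
#'
#' @param profiles Consensus tibble `accession`, `fraction`, `intensity`.
#' @param pairs Tibble `accession_a`, `accession_b`.
#' @return `pairs` with `r` (Pearson, in `[-1, 1]`, symmetric) and a
#'   `degenerate` flag where a zero-variance or missing profile makes r
#'   undefined (`NA`).
#' @export
coelution_correlation <- function(profiles, pairs) {
  wide <- tidyr::pivot_wider(profiles, names_from = "accession",
                             values_from = "intensity")
  wide <- dplyr::arrange(wide, .data$fraction)
  out <- as_tibble(pairs)
  vals <- purrr::map2_dbl(out$accession_a, out$accession_b, function(a, b) {
    if (!a %in% names(wide) || !b %in% names(wide)) return(NA_real_)
    x <- wide[[a]]; y <- wide[[b]]
    if (anyNA(x) || anyNA(y) || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    cor(x, y)
  })
  out$r <- vals
  out$degenerate <- is.na(vals)
  out
}

#' Per-replicate co-elution scores for candidate pairs
#'
#' When no external classifier score table is available, the per-replicate
#' co-elution score defaults to `max(0, r)` of the replicate profiles --
#' a stand-in score on the same `[0, 1]` scale as an external random-forest
#' co-elution classifier would provide, not a re-implementation of one.
#'
#' @param profiles Long tibble `accession`, `replicate`, `fraction`,
#'   `intensity`.
#' @param pairs Tibble `accession_a`, `accession_b`.
#' @return Tibble `accession_a`, `accession_b`, `replicate`, `score`.
#' @export
score_coelution_pairs <- function(profiles, pairs) {
  norm <- normalize_profiles(profiles, mode = "sum")
  purrr::map_dfr(sort(unique(norm$replicate)), function(rep_id) {
    rp <- norm[norm$replicate == rep_id, c("accession", "fraction", "intensity")]
    cc <- coelution_correlation(rp, pairs)
    tibble(accession_a = cc$accession_a, accession_b = cc$accession_b,
           replicate = rep_id,
           score = pmax(0, dplyr::coalesce(cc$r, 0)))
  })
}

#' Fraction-to-apparent-mass calibration curve
#'
#' Log-linear apparent-mass ladder over the gel: fraction 1 is the highest
#' apparent mass. Used to express the "minimum peak elution" filter in kDa.
#'
#' @param n_fractions Number of fractions (default 48).
#' @param mass_range Apparent mass at the first and last fraction, in kDa.
#' @return Tibble `fraction`, `kda`.
#' @export
bn_calibration <- function(n_fractions = 48L, mass_range = c(5000, 10)) {
  tibble(
    fraction = seq_len(n_fractions),
    kda = exp(seq(log(mass_range[1]), log(mass_range[2]),
                  length.out = n_fractions))
  )
}

#' Filter blue-native co-fractionation candidate pairs
#'
#' A candidate pair passes when its co-elution score reaches `score_min` in
#' at least `min_replicates` replicates, its complex has at most
#' `max_complex_size` proteins, and the complex peak elutes at an apparent
#' mass of at least `min_peak_mass_kda` (via the fraction-to-mass
#' calibration). Without a calibration the mass filter is skipped with a
#' warning. The filter is monotone: raising any replicate score never flips
#' a pass to a fail.
#'
#' @param candidates Tibble with `accession_a`, `accession_b`, `replicate`,
#'   `score` and (optionally) `complex_id`, `complex_size`, `peak_fraction`.
#' @param calibration Tibble `fraction`, `kda` (see [bn_calibration()]),
#'   or `NULL`.
#' @param score_min Per-replicate score floor (default 0.7, `>=`).
#' @param min_replicates Replicates required at or above the floor (2).
#' @param max_complex_size Largest admissible complex (25 proteins).
#' @param min_peak_mass_kda Minimal complex peak apparent mass (67 kDa).
#' @return Per-pair tibble with `n_replicates_passing`, complex metadata,
#'   `peak_mass_kda` and the filter verdicts (`passes_score`,
#'   `passes_size`, `passes_mass`, `passes_filters`).
#' @export
filter_bn_candidates <- function(candidates, calibration = NULL,
                                 score_min = 0.7, min_replicates = 2L,
                                 max_complex_size = 25L,
                                 min_peak_mass_kda = 67) {
  cand <- canonicalize_pairs(as_tibble(candidates))
  meta_cols <- intersect(c("complex_id", "complex_size", "peak_fraction"),
                         names(cand))
  out <- dplyr::summarise(
    dplyr::group_by(cand, .data$accession_a, .data$accession_b,
                    !!!rlang::syms(meta_cols)),
    n_replicates_passing = sum(.data$score >= score_min, na.rm = TRUE),
    max_score = max(.data$score, na.rm = TRUE),
    .groups = "drop"
  )
  out$passes_score <- out$n_replicates_passing >= min_replicates
  out$passes_size <- if ("complex_size" %in% names(out)) {
    out$complex_size <= max_complex_size
  } else {
    TRUE
  }
  if (!is.null(calibration) && "peak_fraction" %in% names(out)) {
    out$peak_mass_kda <- exp(approx(calibration$fraction, log(calibration$kda),
                                    xout = out$peak_fraction, rule = 2)$y)
    out$passes_mass <- out$peak_mass_kda >= min_peak_mass_kda
  } else {
    if (is.null(calibration)) {
      warn("no fraction-to-mass calibration supplied; mass filter skipped")
    }
    out$peak_mass_kda <- NA_real_
    out$passes_mass <- TRUE
  }
  out$passes_filters <- out$passes_score & out$passes_size & out$passes_mass
  out
}
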