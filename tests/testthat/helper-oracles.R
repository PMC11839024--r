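# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, longhand formulas.

# Longhand Euclidean distance from a model's residue table.
longhand_distance <- function(res, acc_a, pos_a, acc_b, pos_b) {
  ia <- which(res$accession == acc_a & res$position == pos_a)
  ib <- which(res$accession == acc_b & res$position == pos_b)
  if (length(ia) != 1 || length(ib) != 1) return(NA_real_)
  sqrt(sum((c(res$x[ia], res$y[ia], res$z[ia]) -
              c(res$x[ib], res$y[ib], res$z[ib]))^2))
}

# Brute-force ROC point set: threshold sweep over all observed values.
brute_roc_points <- function(metric, labels) {
  thr <- sort(unique(metric))
  pts <- t(vapply(thr, function(t) {
    pred <- metric >= t
    c(fpr = mean(pred[!labels]), tpr = mean(pred[labels]))
  }, numeric(2)))
  pts <- rbind(c(fpr = 1, tpr = 1), pts, c(fpr = 0, tpr = 0))
  unique(as.data.frame(pts))
}

# O(n^3) triangle enumeration on an edge table with xl_count.
brute_triangles <- function(edges, require_xl = TRUE) {
  nodes <- sort(unique(c(edges$accession_a, edges$accession_b)))
  key <- paste(pmin(edges$accession_a, edges$accession_b),
               pmax(edges$accession_a, edges$accession_b))
  xl <- tapply(edges$xl_count, key, max)
  has_edge <- function(a, b) paste(min(a, b), max(a, b)) %in% key
  xl_of <- function(a, b) unname(xl[paste(min(a, b), max(a, b))])
  out <- list()
  n <- length(nodes)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- nodes[i]; b <- nodes[j]; c <- nodes[k]
      if (has_edge(a, b) && has_edge(a, c) && has_edge(b, c)) {
        n_xl <- sum(c(xl_of(a, b), xl_of(a, c), xl_of(b, c)) >= 1)
        if (!require_xl || n_xl >= 1) {
          out[[length(out) + 1]] <- data.frame(
            accession_a = a, accession_b = b, accession_c = c,
            n_xl_edges = n_xl)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(accession_a = character(), accession_b = character(),
                      accession_c = character(), n_xl_edges = integer()))
  }
  do.call(rbind, out)
}

# Tiny igraph builder from an edge tibble with evidence columns.
toy_graph <- function(edges) {
  build_network(
    edges[c("accession_a", "accession_b", "xl_count")],
    if ("bn_count" %in% names(edges)) {
      e <- edges[edges$bn_count > 0, ]
      data.frame(accession_a = e$accession_a, accession_b = e$accession_b,
                 n_replicates_passing = e$bn_count)
    } else {
      NULL
    }
  )
}
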