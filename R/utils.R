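#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor median glm binomial rnorm runif setNames approx
#' @importFrom utils head
NULL

# Named RNG substream: one integer seed plus a stream name gives an
# independent, stable seed (< 2^31), so adding a generator never perturbs
# the draws of another.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  chars <- utf8ToInt(name)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1048573) * 1009 + h) %% 2147483629L + 1L
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# Canonical unordered-pair ordering: accession_a <= accession_b and, for
# self pairs, pos_a <= pos_b. Makes duplicate collapse deterministic and
# output invariant to input row order.
canonicalize_pairs <- function(df, a = "accession_a", b = "accession_b",
                               pa = NULL, pb = NULL) {
  swap <- df[[a]] > df[[b]]
  if (!is.null(pa)) {
    swap <- swap | (df[[a]] == df[[b]] & df[[pa]] > df[[pb]])
  }
  if (any(swap)) {
    tmp <- df[[a]][swap]
    df[[a]][swap] <- df[[b]][swap]
    df[[b]][swap] <- tmp
    if (!is.null(pa)) {
      tmp <- df[[pa]][swap]
      df[[pa]][swap] <- df[[pb]][swap]
      df[[pb]][swap] <- tmp
    }
  }
  df
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}
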