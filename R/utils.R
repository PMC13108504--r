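#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd median cor cor.test quantile setNames
#' @importFrom utils head
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit seed derived from a base seed and arbitrary string keys.
# Polynomial string hash; stable across platforms and evaluation order.
derive_seed <- function(seed, ...) {
  keys <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                collapse = "\r")
  h <- 0
  m <- 2147483629
  for (cp in utf8ToInt(keys)) h <- (h * 131 + cp) %% m
  as.integer(h %% 2147483398L + 1L)
}

check_number <- function(x, name, lower = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)) || x < lower) {
    abort(sprintf("`%s` must be a single %snumber%s.", name,
                  if (finite) "finite " else "",
                  if (is.finite(lower)) sprintf(" >= %s", lower) else ""),
          class = "ratmind_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower),
          class = "ratmind_invalid_argument")
  }
  invisible(as.integer(x))
}

abort_invalid <- function(msg) abort(msg, class = "ratmind_invalid_argument")
abort_format <- function(msg) abort(msg, class = "ratmind_format_error")
abort_pipeline <- function(msg) abort(msg, class = "ratmind_pipeline_error")

# Unique unordered pairs of `labels`, in the (a < b) order induced by the
# label vector itself (not alphabetical), as a two-column tibble.
label_pairs <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(region_a = labels[idx[, 1L]], region_b = labels[idx[, 2L]])
}

# Extract the upper-triangle values of a labelled square matrix in the same
# order as label_pairs(rownames(m)).
upper_values <- function(m) m[upper.tri(m)]
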