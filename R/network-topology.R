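#' Nodal strength of a weighted network
#'
#' Strength `s` of a region is the sum of its incident edge weights,
#' excluding the self-similarity diagonal.
#'
#' @param network A `mind_network`.
#' @return Tibble with columns `region`, `strength`.
#' @export
nodal_strength <- function(network) {
  w <- as.matrix(network)
  s <- colSums(w) - diag(w)
  tibble::tibble(region = colnames(w), strength = unname(s))
}

#' Network hubs: the top-k regions by strength
#'
#' Ties are broken by ascending region label so the hub set is deterministic.
#'
#' @param strengths Tibble from [nodal_strength()].
#' @param k Number of hubs. Default 10.
#' @return Character vector of k region labels, strongest first.
#' @export
top_hubs <- function(strengths, k = 10) {
  k <- check_count(k, "k")
  if (k > nrow(strengths)) {
    abort_invalid(sprintf("k = %d exceeds the %d regions available.",
                          k, nrow(strengths)))
  }
  ord <- order(-strengths$strength, strengths$region)
  strengths$region[ord][seq_len(k)]
}

#' Weighted rich-club coefficient
#'
#' `phi = W_club / W_max`, where `W_club` is the sum of edge weights over all
#' unordered hub-hub pairs and `W_max` is the sum of the equally many
#' strongest edge weights anywhere in the network. `phi = 1` when the hub
#' interconnections are exactly the network's strongest edges. The ordered
#' hub-pair count (`k * (k - 1)`, e.g. 90 for 10 hubs) is reported alongside
#' the unordered count used in the sums, matching the convention in which
#' hub interconnections are counted directionally.
#'
#' @param network A `mind_network`.
#' @param hubs Character vector of hub labels (>= 2), e.g. from
#'   [top_hubs()].
#' @return A list of class `rich_club_result`: `phi`, `hubs`,
#'   `W_club`, `W_max`, `n_hub_pairs` (unordered),
#'   `n_hub_pairs_ordered`.
#' @export
rich_club <- function(network, hubs) {
  w <- as.matrix(network)
  if (length(hubs) < 2L) abort_invalid("Need at least 2 hubs.")
  if (!all(hubs %in% colnames(w))) {
    abort_invalid(sprintf("Hub(s) not in the network: %s.",
                          paste(setdiff(hubs, colnames(w)), collapse = ", ")))
  }
  sub <- w[hubs, hubs, drop = FALSE]
  club_weights <- sub[upper.tri(sub)]
  m <- length(club_weights)
  all_weights <- sort(upper_values(w), decreasing = TRUE)
  W_club <- sum(club_weights)
  W_max <- sum(all_weights[seq_len(m)])
  structure(
    list(phi = W_club / W_max, hubs = hubs, W_club = W_club, W_max = W_max,
         n_hub_pairs = m, n_hub_pairs_ordered = 2L * m),
    class = "rich_club_result"
  )
}

#' @export
print.rich_club_result <- function(x, ...) {
  cat(sprintf("<rich_club> phi = %.3f (%d hubs, %d ordered hub pairs)\n",
              x$phi, length(x$hubs), x$n_hub_pairs_ordered))
  invisible(x)
}

#' @method tidy rich_club_result
#' @export
tidy.rich_club_result <- function(x, ...) {
  tibble::tibble(phi = x$phi, W_club = x$W_club, W_max = x$W_max,
                 n_hubs = length(x$hubs), n_hub_pairs = x$n_hub_pairs,
                 n_hub_pairs_ordered = x$n_hub_pairs_ordered)
}
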