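#' Topological (rank-based) nearest neighbours
#'
#' Returns the indices of the `M` Euclidean nearest neighbours of agent `i`
#' among the rows of `positions`, sorted by (distance, index); distance ties
#' are broken by the lower agent index. With `include_self = TRUE` the focal
#' agent itself is part of the candidate set (and, being at distance zero,
#' always selected first).
#'
#' @param positions N x D matrix of agent positions, metres.
#' @param i Focal agent index.
#' @param M Number of neighbours to return.
#' @param include_self Whether the focal agent may appear in the result.
#' @return Integer vector of length `M`.
#' @examples
#' p <- rbind(c(0, 0), c(1, 0), c(3, 0))
#' knn_topological(p, i = 1, M = 2)
#' @export
knn_topological <- function(positions, i, M, include_self = FALSE) {
  N <- nrow(positions)
  max_m <- if (include_self) N else N - 1L
  if (M < 0 || M > max_m) stopf("M must be in 0..%d", max_m)
  if (M == 0) return(integer(0))
  d <- sqrt(colSums((t(positions) - positions[i, ])^2))
  cand <- seq_len(N)
  if (!include_self) {
    cand <- cand[-i]
    d <- d[-i]
  }
  ord <- order(d, cand)
  cand[ord][seq_len(M)]
}

# neighbour index matrix for all agents at once: row i = the M nearest
# neighbours of i (plus i itself first when include_self). Ties broken by
# lower index.
knn_all <- function(positions, M, include_self = FALSE) {
  N <- nrow(positions)
  dmat <- as.matrix(stats::dist(positions))
  if (include_self) {
    out <- matrix(NA_integer_, N, M + 1L)
    for (i in seq_len(N)) {
      d <- dmat[i, ]
      d[i] <- -Inf                        # self always first
      out[i, ] <- order(d, seq_len(N))[seq_len(M + 1L)]
    }
  } else {
    out <- matrix(NA_integer_, N, M)
    if (M == 0) return(out)
    for (i in seq_len(N)) {
      d <- dmat[i, ]
      d[i] <- Inf
      out[i, ] <- order(d, seq_len(N))[seq_len(M)]
    }
  }
  out
}
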