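# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. All exported stochastic functions route
# through this so nothing in the package consumes global random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

cosine_dist <- function(u, v) 1 - cosine_sim(u, v)

#' Edge index for the upper triangle of an N-node graph
#'
#' Enumerates all unordered node pairs (i, j) with i < j in row-major order
#' over the upper triangle: (1,2), (1,3), ..., (1,N), (2,3), ... This fixed
#' ordering defines the edge-to-row mapping used by edge time series,
#' edge-community labels and semantic-network edge vectors throughout the
#' package.
#'
#' @param n number of nodes (at least 2).
#' @return An E x 2 integer matrix with columns \code{i} and \code{j}, where
#'   E = n(n-1)/2.
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) seq.int(a + 1L, n)),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# Number of nodes implied by an edge count E = n(n-1)/2.
nodes_from_edges <- function(E) {
  n <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(n - round(n)) > 1e-8)
    stop("edge count ", E, " does not correspond to a complete graph",
         call. = FALSE)
  as.integer(round(n))
}

# Extract the upper-triangle edge weight vector of a symmetric matrix in
# edge_index() order.
edge_vector <- function(w, idx = edge_index(nrow(w))) {
  w[cbind(idx[, 1L], idx[, 2L])]
}

# Rebuild a symmetric matrix (unit diagonal by default) from an edge vector.
edge_matrix <- function(ev, n, idx = edge_index(n), diag_value = 1) {
  w <- matrix(diag_value, n, n)
  w[cbind(idx[, 1L], idx[, 2L])] <- ev
  w[cbind(idx[, 2L], idx[, 1L])] <- ev
  diag(w) <- diag_value
  w
}
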