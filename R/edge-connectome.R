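# Edge-centric functional connectivity: co-fluctuation (edge) time series
# from z-scored parcellated BOLD, edge-community detection by k-means, and
# node-level maps of community overlap (normalized entropy) and community
# similarity aggregated over atlas networks.

#' Construct a region-by-time BOLD matrix
#'
#' @param mat numeric matrix, regions in rows, time points in columns.
#' @param atlas optional character vector of network labels, one per region.
#' @param subject,condition,trial optional identifiers.
#' @param z_scored has each row already been standardized (population SD)?
#' @return A list of class \code{"region_ts"}.
#' @export
region_ts <- function(mat, atlas = NULL, subject = NA, condition = NA,
                      trial = NA, z_scored = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 regions", call. = FALSE)
  if (ncol(mat) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (!is.null(atlas) && length(atlas) != nrow(mat))
    stop("'atlas' must have one label per region", call. = FALSE)
  structure(list(mat = mat, atlas = atlas, subject = subject,
                 condition = condition, trial = trial,
                 z_scored = isTRUE(z_scored)),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("Region time series: ", nrow(x$mat), " regions x ", ncol(x$mat),
      " time points", if (x$z_scored) " (z-scored)", "\n", sep = "")
  invisible(x)
}

#' Z-score each region's time series
#'
#' Standardizes every row to mean 0 and population standard deviation 1
#' (divisor T, not T-1). The population convention matters downstream: it
#' makes the time average of each edge co-fluctuation series equal the
#' Pearson correlation of the region pair exactly.
#'
#' @param ts a [region_ts()].
#' @return The z-scored \code{"region_ts"} (\code{z_scored = TRUE}).
#' @export
zscore <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  m <- ts$mat
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  if (any(sd_pop == 0))
    stop("zero-variance region(s): ",
         paste(which(sd_pop == 0), collapse = ", "), call. = FALSE)
  ts$mat <- centered / sd_pop
  ts$z_scored <- TRUE
  ts
}

#' Concatenate z-scored trials in time
#'
#' Each trial is z-scored before concatenation (so every trial contributes
#' with unit variance), then columns are joined in trial order.
#'
#' @param trials list of [region_ts()] objects sharing region count and
#'   atlas; trials not yet z-scored are z-scored first.
#' @return A single \code{"region_ts"} with \code{T = sum of trial lengths}.
#' @export
concatenate_trials <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  trials <- lapply(trials, function(tr) {
    stopifnot(inherits(tr, "region_ts"))
    if (tr$z_scored) tr else zscore(tr)
  })
  ns <- vapply(trials, function(tr) nrow(tr$mat), integer(1))
  if (length(unique(ns)) != 1L)
    stop("trials disagree on region count: ", paste(ns, collapse = ", "),
         call. = FALSE)
  first <- trials[[1L]]
  for (tr in trials[-1L])
    if (!identical(tr$atlas, first$atlas))
      stop("trials disagree on atlas labels", call. = FALSE)
  out <- first
  out$mat <- do.call(cbind, lapply(trials, `[[`, "mat"))
  out$trial <- NA
  out
}

#' Elementwise difference of two matched region time series
#'
#' Subtracts condition \code{b} from condition \code{a} time point by time
#' point, isolating activity specific to one condition. The result is
#' flagged non-z-scored; downstream stages re-standardize as needed.
#'
#' @param a,b [region_ts()] objects of identical shape.
#' @return A \code{"region_ts"} with \code{condition = "difference"}.
#' @export
condition_difference <- function(a, b) {
  stopifnot(inherits(a, "region_ts"), inherits(b, "region_ts"))
  if (!identical(dim(a$mat), dim(b$mat)))
    stop("shape mismatch: ", paste(dim(a$mat), collapse = "x"), " vs ",
         paste(dim(b$mat), collapse = "x"), call. = FALSE)
  out <- a
  out$mat <- a$mat - b$mat
  out$z_scored <- FALSE
  out$condition <- "difference"
  out
}

#' Edge co-fluctuation time series
#'
#' For every unordered region pair (i, j), the standardized time series
#' \eqn{z_i} and \eqn{z_j} are multiplied point by point, giving the
#' instantaneous co-fluctuation of the pair: positive when both regions
#' deflect the same way, negative when they deflect oppositely. With
#' population-SD z-scoring, the time average of each edge series equals the
#' pair's Pearson correlation.
#'
#' @param z a z-scored [region_ts()].
#' @return An \code{"edge_ts"}: list with \code{mat} (E x T matrix in
#'   [edge_index()] row order), \code{index}, \code{n_nodes}, \code{atlas}
#'   and \code{provenance}.
#' @export
edge_time_series <- function(z) {
  stopifnot(inherits(z, "region_ts"))
  if (!z$z_scored)
    stop("input must be z-scored (see zscore())", call. = FALSE)
  n <- nrow(z$mat)
  idx <- edge_index(n)
  mat <- z$mat[idx[, 1L], , drop = FALSE] * z$mat[idx[, 2L], , drop = FALSE]
  structure(list(mat = mat, index = idx, n_nodes = n, atlas = z$atlas,
                 provenance = list(subject = z$subject,
                                   condition = z$condition)),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat("Edge time series: ", nrow(x$mat), " edges (", x$n_nodes,
      " nodes) x ", ncol(x$mat), " time points\n", sep = "")
  invisible(x)
}

#' Average edge time series across subjects
#'
#' Elementwise mean over subjects, producing the representative
#' co-fluctuation matrix used for group-level community detection.
#'
#' @param ets_list list of \code{"edge_ts"} objects with identical
#'   dimensions.
#' @return An \code{"edge_ts"} with provenance \code{"group-average"}.
#' @export
group_average <- function(ets_list) {
  stopifnot(is.list(ets_list), length(ets_list) >= 1L)
  for (e in ets_list) stopifnot(inherits(e, "edge_ts"))
  ts_lens <- vapply(ets_list, function(e) ncol(e$mat), integer(1))
  es <- vapply(ets_list, function(e) nrow(e$mat), integer(1))
  if (length(unique(ts_lens)) != 1L || length(unique(es)) != 1L)
    stop("edge time series disagree in size; per-subject T: ",
         paste(ts_lens, collapse = ", "), "; E: ",
         paste(es, collapse = ", "), call. = FALSE)
  out <- ets_list[[1L]]
  out$mat <- Reduce(`+`, lapply(ets_list, `[[`, "mat")) / length(ets_list)
  out$provenance <- "group-average"
  out
}

#' Edge functional connectivity matrix
#'
#' Similarity between every pair of edge time series. In
#' \code{"inner-product"} mode entry (e, f) is the normalized inner product
#' \eqn{\sum_t e(t) f(t) / \sqrt{\sum e^2 \sum f^2}} (the co-fluctuation
#' analogue of unwrapped Pearson correlation); \code{"pearson"} mode centers
#' each edge series first. Zero-norm edge rows yield 0 entries with a
#' warning.
#'
#' @param ets an \code{"edge_ts"}.
#' @param normalization similarity normalization.
#' @return An \code{"edge_fc"}: list with the E x E \code{mat} (symmetric,
#'   unit diagonal) and the normalization used.
#' @export
edge_fc <- function(ets, normalization = c("inner-product", "pearson")) {
  stopifnot(inherits(ets, "edge_ts"))
  normalization <- match.arg(normalization)
  m <- ets$mat
  if (ncol(m) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (normalization == "pearson") m <- m - rowMeans(m)
  norms <- sqrt(rowSums(m^2))
  bad <- norms == 0
  if (any(bad)) {
    warning(sum(bad), " zero-norm edge row(s); their similarities set to 0")
    norms[bad] <- 1
  }
  s <- tcrossprod(m / norms)
  if (any(bad)) {
    s[bad, ] <- 0
    s[, bad] <- 0
  }
  diag(s) <- 1
  structure(list(mat = s, normalization = normalization, index = ets$index),
            class = "edge_fc")
}

#' Detect edge communities by k-means over a range of k
#'
#' Clusters the edge time series directly (squared Euclidean distance on the
#' E x T matrix, no intermediate similarity reduction) for each k in
#' \code{k_range}, keeping the best of \code{restarts} random
#' initializations per k. The per-restart iteration cap is high (default
#' 5000) so every restart runs to convergence. Degenerate inputs with fewer
#' distinct edge rows than k are labeled by matching distinct row patterns
#' (the surplus clusters stay empty), with a message.
#'
#' @param ets an \code{"edge_ts"}.
#' @param k_range integer vector of community counts.
#' @param restarts random initializations per k.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed; labels are deterministic given it.
#' @return An \code{"edge_communities"}: list with \code{labels} (list over
#'   k of integer edge labels), \code{inertia} (total within-cluster sum of
#'   squares per k), \code{k_range}, \code{index}, \code{n_nodes},
#'   \code{atlas}, \code{seed}.
#' @export
cluster_edges <- function(ets, k_range = 2:20, restarts = 10L,
                          max_iter = 5000L, seed = 1L) {
  stopifnot(inherits(ets, "edge_ts"))
  k_range <- as.integer(k_range)
  if (any(k_range < 1L)) stop("k must be >= 1", call. = FALSE)
  E <- nrow(ets$mat)
  if (E < max(k_range))
    stop("need at least max(k_range) = ", max(k_range), " edges, got ", E,
         call. = FALSE)
  uniq <- unique(ets$mat)
  labels <- vector("list", length(k_range))
  inertia <- numeric(length(k_range))
  names(labels) <- names(inertia) <- paste0("k", k_range)
  with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      if (nrow(uniq) < k) {
        # fewer distinct rows than clusters: label by row pattern
        key <- apply(ets$mat, 1L, paste, collapse = "\r")
        lab <- match(key, apply(uniq, 1L, paste, collapse = "\r"))
        message("k = ", k, ": only ", nrow(uniq),
                " distinct edge rows; surplus clusters left empty")
        labels[[ki]] <- as.integer(lab)
        inertia[ki] <- 0
        next
      }
      fit <- NULL
      for (attempt in 1:20) {
        fit <- tryCatch(
          stats::kmeans(ets$mat, centers = k, iter.max = max_iter,
                        nstart = restarts),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit))
        stop("k-means failed to produce ", k,
             " nonempty clusters after 20 re-initializations", call. = FALSE)
      labels[[ki]] <- as.integer(fit$cluster)
      inertia[ki] <- fit$tot.withinss
    }
  })
  structure(list(labels = labels, inertia = inertia, k_range = k_range,
                 index = ets$index, n_nodes = ets$n_nodes, atlas = ets$atlas,
                 seed = seed),
            class = "edge_communities")
}

#' @export
print.edge_communities <- function(x, ...) {
  cat("Edge communities: ", length(x$labels[[1L]]), " edges, k in {",
      paste(range(x$k_range), collapse = ".."), "}\n", sep = "")
  invisible(x)
}

#' Node-by-node matrix of edge-community labels
#'
#' Rearranges the per-edge community labels for one k into an N x N matrix X
#' where entry (i, j) is the community of edge (i, j). The diagonal is empty
#' (NA): self-connections are not considered. Column i of X lists every
#' community node i participates in — the overlapping node-community
#' profile.
#'
#' @param communities an \code{"edge_communities"} from [cluster_edges()],
#'   or directly an integer label vector in [edge_index()] order.
#' @param k which community count to extract (required for
#'   \code{"edge_communities"} input; for a raw label vector it names the
#'   normalizer used downstream).
#' @return An N x N integer matrix of class \code{"node_community_matrix"}
#'   with attribute \code{k}.
#' @export
node_community_matrix <- function(communities, k) {
  if (inherits(communities, "edge_communities")) {
    key <- paste0("k", k)
    if (!key %in% names(communities$labels))
      stop("no labels for k = ", k, call. = FALSE)
    labels <- communities$labels[[key]]
    n <- communities$n_nodes
    idx <- communities$index
  } else {
    labels <- as.integer(communities)
    n <- nodes_from_edges(length(labels))
    idx <- edge_index(n)
  }
  x <- matrix(NA_integer_, n, n)
  x[cbind(idx[, 1L], idx[, 2L])] <- labels
  x[cbind(idx[, 2L], idx[, 1L])] <- labels
  structure(x, k = as.integer(k), class = c("node_community_matrix", "matrix"))
}

#' Normalized entropy of a node's edge-community memberships
#'
#' For node i, let \eqn{p_c} be the fraction of its N-1 incident edges
#' carrying community label c. The normalized entropy
#' \eqn{-\sum_c p_c \log p_c / \log k} (natural log; 0 log 0 := 0) measures
#' how widely the node's edges are spread over communities: 0 when all its
#' edges share one community (no overlap), 1 when they are spread uniformly
#' over all k communities (maximal overlap).
#'
#' @param x a \code{"node_community_matrix"} (or plain square label matrix
#'   with NA diagonal).
#' @param k number of communities used as normalizer; defaults to the
#'   matrix's \code{k} attribute.
#' @return Numeric vector of per-node entropies in [0, 1].
#' @examples
#' x <- node_community_matrix(c(1L, 2L, 2L), k = 2)
#' overlap_entropy(x)
#' @export
overlap_entropy <- function(x, k = attr(x, "k")) {
  if (is.null(k)) stop("'k' is required", call. = FALSE)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2 (log k normalizer undefined)",
                   call. = FALSE)
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    labs <- x[, i][-i]
    p <- tabulate(labs, nbins = max(labs, k)) / length(labs)
    p <- p[p > 0]
    -sum(p * log(p)) / log(k)
  }, numeric(1))
}

#' Edge-community similarity between node profiles
#'
#' The similarity of nodes i and j is the proportion of positions m at which
#' their community-label columns agree, \eqn{x_{mi} = x_{mj}}. Positions i
#' and j themselves are excluded (the diagonal of X is empty), so the
#' comparison runs over the N-2 remaining nodes. Optionally each node's
#' similarities are averaged over the other nodes of its own atlas network,
#' giving the per-node within-network community-similarity map.
#'
#' @param x a \code{"node_community_matrix"}.
#' @param atlas optional character vector of network labels per node; when
#'   supplied, per-node within-network mean similarities are returned too.
#' @param include_pair also count the mutual position (the label of edge
#'   (i, j) compared with itself, which always matches), giving denominator
#'   N-1; off by default, kept for sensitivity checks.
#' @return A list with \code{similarity} (N x N symmetric matrix, unit
#'   diagonal) and, when \code{atlas} is given, \code{node_mean} (per-node
#'   within-network mean; NA for single-node networks) and \code{network}.
#' @export
community_similarity <- function(x, atlas = NULL, include_pair = FALSE) {
  n <- nrow(x)
  labs <- sort(unique(as.integer(x[!is.na(x)])))
  agree <- matrix(0, n, n)
  for (c in labs) {
    ind <- (x == c)
    ind[is.na(ind)] <- FALSE
    agree <- agree + crossprod(ind)
  }
  # Columns i and j have NA at rows i and j, so positions i and j never
  # count as agreements: 'agree' already sums over the N-2 valid positions.
  if (include_pair) {
    s <- (agree + 1) / (n - 1)
  } else {
    s <- agree / (n - 2)
  }
  diag(s) <- 1
  out <- list(similarity = s)
  if (!is.null(atlas)) {
    if (length(atlas) != n)
      stop("'atlas' must have one label per node", call. = FALSE)
    node_mean <- vapply(seq_len(n), function(i) {
      peers <- setdiff(which(atlas == atlas[i]), i)
      if (length(peers) == 0L) return(NA_real_)
      mean(s[i, peers])
    }, numeric(1))
    out$node_mean <- node_mean
    out$network <- atlas
  }
  out
}

#' Per-node overlap profile for one community count
#'
#' Combines [overlap_entropy()] and [community_similarity()] for a single k
#' into a per-node table.
#'
#' @param communities an \code{"edge_communities"}.
#' @param k community count to profile.
#' @param atlas network labels per node; defaults to those carried on the
#'   clustering input.
#' @return A data.frame of class \code{"overlap_profile"} with columns
#'   \code{node}, \code{network}, \code{entropy}, \code{similarity}
#'   (within-network mean; NA if no atlas), and attribute \code{k}.
#' @export
community_profile <- function(communities, k, atlas = communities$atlas) {
  x <- node_community_matrix(communities, k)
  ent <- overlap_entropy(x, k)
  sim <- community_similarity(x, atlas = atlas)
  out <- data.frame(
    node = seq_len(nrow(x)),
    network = if (is.null(atlas)) NA_character_ else atlas,
    entropy = ent,
    similarity = if (is.null(atlas)) NA_real_ else sim$node_mean,
    stringsAsFactors = FALSE)
  structure(out, k = as.integer(k), class = c("overlap_profile", "data.frame"))
}

#' Average overlap profiles across community counts
#'
#' Single-k community structure is arbitrary; the robust spatial pattern is
#' the elementwise mean of the per-node entropy and similarity maps across
#' the whole k range.
#'
#' @param profiles list of \code{"overlap_profile"} data.frames sharing the
#'   same nodes (one per k).
#' @return An \code{"overlap_profile"} with per-node means over k and
#'   attribute \code{k} set to \code{"mean"} plus \code{k_range}.
#' @export
average_over_k <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  nodes <- profiles[[1L]]$node
  for (p in profiles)
    if (!identical(p$node, nodes))
      stop("profiles disagree on nodes", call. = FALSE)
  out <- profiles[[1L]]
  out$entropy <- rowMeans(vapply(profiles, `[[`, numeric(length(nodes)),
                                 "entropy"))
  out$similarity <- rowMeans(vapply(profiles, `[[`, numeric(length(nodes)),
                                    "similarity"))
  ks <- vapply(profiles, function(p) attr(p, "k") %||% NA_integer_,
               integer(1))
  attr(out, "k") <- "mean"
  attr(out, "k_range") <- ks
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full overlap analysis over a k range
#'
#' Convenience wrapper: profiles every k of a clustering and averages the
#' maps over the range.
#'
#' @param communities an \code{"edge_communities"}.
#' @param atlas network labels per node.
#' @return The averaged \code{"overlap_profile"}.
#' @export
overlap_profiles <- function(communities, atlas = communities$atlas) {
  profs <- lapply(communities$k_range, function(k)
    community_profile(communities, k, atlas = atlas))
  average_over_k(profs)
}
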