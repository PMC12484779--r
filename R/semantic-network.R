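# Semantic networks from word embeddings and their percolation-based
# robustness: the percolation integral (PI) plus two null analyses (edge
# noise and link shuffling) that separate structural from weight-driven
# effects.

#' Build a fully connected semantic network from a token stream
#'
#' Nodes are the unique in-vocabulary words of the stream (duplicates
#' collapsed); the weight of every edge is the Pearson correlation between
#' the two words' embedding vectors, with sign retained. The network is the
#' substrate for percolation analysis.
#'
#' @param tokens a \code{"token_sequence"} or character vector of tokens.
#' @param lexicon an \code{"embedding_lexicon"}.
#' @return A \code{"semantic_network"}: list with \code{nodes} (character),
#'   \code{weights} (symmetric node x node correlation matrix, unit
#'   diagonal by convention but never used as an edge) and \code{n_edges}.
#' @export
build_semantic_network <- function(tokens, lexicon) {
  if (is.character(tokens)) tokens <- token_sequence(tokens)
  stopifnot(inherits(tokens, "token_sequence"),
            inherits(lexicon, "embedding_lexicon"))
  words <- unique(tokens$tokens)
  words <- words[words %in% rownames(lexicon)]
  if (length(words) < 3L)
    stop("need at least 3 unique in-vocabulary words, got ", length(words),
         call. = FALSE)
  vecs <- lexicon[words, , drop = FALSE]
  sds <- apply(vecs, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance embedding vector for token(s): ",
         paste(words[sds == 0], collapse = ", "), call. = FALSE)
  w <- stats::cor(t(vecs))
  dimnames(w) <- list(words, words)
  semantic_network(w)
}

#' Construct a semantic network from a weight matrix
#'
#' @param weights symmetric numeric matrix of signed edge weights in
#'   [-1, 1]; the diagonal is ignored (no self-edges).
#' @return A \code{"semantic_network"}.
#' @export
semantic_network <- function(weights) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 2L || ncol(weights) != n)
    stop("'weights' must be a square matrix with >= 2 nodes", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("'weights' must be symmetric", call. = FALSE)
  off <- weights[upper.tri(weights)]
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8))
    stop("edge weights must lie in [-1, 1]", call. = FALSE)
  nodes <- rownames(weights)
  if (is.null(nodes)) nodes <- paste0("w", seq_len(n))
  diag(weights) <- 1
  structure(list(nodes = nodes, weights = weights,
                 n_edges = (n * (n - 1L)) %/% 2L),
            class = "semantic_network")
}

#' @export
print.semantic_network <- function(x, ...) {
  ev <- edge_vector(x$weights)
  cat("Semantic network: ", length(x$nodes), " nodes, ", x$n_edges,
      " edges\n  weight range [", format(min(ev), digits = 3), ", ",
      format(max(ev), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Percolation analysis configuration
#'
#' @param start_th,end_th threshold range endpoints.
#' @param th_res threshold resolution (grid step); the default grid 0 to 1 in
#'   steps of 0.0125 evaluates 81 thresholds.
#' @param gc_min stopping size: evaluation stops at the first threshold where
#'   the giant component falls below this many nodes.
#' @param include_stop_term include the stopping threshold's GC term in the
#'   integral? Excluded by default (the iteration stops there); the flag
#'   exists for sensitivity analysis.
#' @return A list of class \code{"percolation_config"}.
#' @export
percolation_config <- function(start_th = 0, end_th = 1, th_res = 0.0125,
                               gc_min = 3L, include_stop_term = FALSE) {
  if (start_th >= end_th) stop("'start_th' must be < 'end_th'", call. = FALSE)
  if (th_res <= 0) stop("'th_res' must be > 0", call. = FALSE)
  structure(list(start_th = start_th, end_th = end_th, th_res = th_res,
                 gc_min = as.integer(gc_min),
                 include_stop_term = isTRUE(include_stop_term)),
            class = "percolation_config")
}

# Size of the giant component among non-isolated nodes given an edge list
# (two-column matrix of node indices); 0 if no edges remain.
giant_component_size <- function(edges, n) {
  if (nrow(edges) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  as.integer(max(igraph::components(g)$csize))
}

#' Percolation analysis of a semantic network
#'
#' Sweeps a threshold grid from \code{start_th} to \code{end_th} in steps of
#' \code{th_res}. At each threshold, edges with weight strictly below the
#' threshold are removed and the giant component (largest connected set of
#' nodes among remaining edges; isolated nodes do not count) is recorded.
#' Evaluation stops at the first threshold where the giant component has
#' fewer than \code{gc_min} nodes; that threshold's term is not added. The
#' percolation integral is
#' \deqn{PI = \sum_{TH} GC(TH) \cdot TH_{res}}
#' over the evaluated thresholds — the area under the giant-component curve,
#' operationalizing the robustness (flexibility) of the network.
#'
#' @param net a \code{"semantic_network"}.
#' @param cfg a [percolation_config()].
#' @return A \code{"percolation"}: list with \code{thresholds} and
#'   \code{gc_sizes} for every visited threshold (including the stopping
#'   one, if any), \code{counted} (logical, which terms entered the
#'   integral), \code{pi}, \code{stopped} and the config.
#' @examples
#' w <- matrix(1, 5, 5)
#' percolate(semantic_network(w))$pi  # 5 * 81 * 0.0125
#' @export
percolate <- function(net, cfg = percolation_config()) {
  stopifnot(inherits(net, "semantic_network"),
            inherits(cfg, "percolation_config"))
  n <- length(net$nodes)
  idx <- edge_index(n)
  ev <- edge_vector(net$weights, idx)
  n_steps <- round((cfg$end_th - cfg$start_th) / cfg$th_res)
  grid <- cfg$start_th + cfg$th_res * (0:n_steps)
  gc_sizes <- integer(0)
  thresholds <- numeric(0)
  stopped <- FALSE
  for (th in grid) {
    keep <- ev >= th - 1e-12   # strict removal of weights < th, fp-safe
    gc <- giant_component_size(idx[keep, , drop = FALSE], n)
    thresholds <- c(thresholds, th)
    gc_sizes <- c(gc_sizes, gc)
    if (gc < cfg$gc_min) {
      stopped <- TRUE
      break
    }
  }
  counted <- rep(TRUE, length(gc_sizes))
  if (stopped && !cfg$include_stop_term)
    counted[length(counted)] <- FALSE
  pi_val <- sum(gc_sizes[counted]) * cfg$th_res
  structure(list(thresholds = thresholds, gc_sizes = gc_sizes,
                 counted = counted, pi = pi_val, stopped = stopped,
                 config = cfg),
            class = "percolation")
}

#' @export
print.percolation <- function(x, ...) {
  cat("Percolation: PI = ", format(x$pi, digits = 6), " over ",
      sum(x$counted), " thresholds",
      if (x$stopped) " (stopped early)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.percolation <- function(x, ...) {
  plot(x$thresholds, x$gc_sizes, type = "s", xlab = "threshold",
       ylab = "giant component size", ...)
  invisible(x)
}

new_robustness <- function(pi_values, mode, params, seed, touched = NULL) {
  structure(list(pi_mean = mean(pi_values), pi_values = pi_values,
                 mode = mode, params = params, seed = seed,
                 touched = touched),
            class = "robustness")
}

#' @export
print.robustness <- function(x, ...) {
  cat("Robustness (", x$mode, "): mean PI = ",
      format(x$pi_mean, digits = 6), " over ", length(x$pi_values),
      " realizations\n", sep = "")
  invisible(x)
}

#' Percolation robustness under edge-weight noise
#'
#' Repeats the percolation analysis on noisy copies of the network. In each
#' realization a single noise standard deviation is drawn uniformly from
#' \code{sd_range} and independent zero-mean Gaussian noise of that SD is
#' added to every edge weight (symmetrically, no clipping) before
#' percolating. The default SD range is \code{[1/E, 10/E]} for a network
#' with E edges. A robustness value close to the noiseless PI indicates a
#' stable percolation process.
#'
#' @param net a \code{"semantic_network"}.
#' @param cfg a [percolation_config()].
#' @param n_real number of noise realizations.
#' @param seed integer seed.
#' @param sd_range length-2 numeric; defaults to \code{c(1, 10) / n_edges}.
#' @return A \code{"robustness"} with \code{mode = "noise"}: per-realization
#'   PIs and their mean.
#' @export
noise_robustness <- function(net, cfg = percolation_config(), n_real = 500L,
                             seed = 1L, sd_range = NULL) {
  stopifnot(inherits(net, "semantic_network"))
  n_real <- as.integer(n_real)
  if (is.na(n_real) || n_real < 1L) stop("'n_real' must be >= 1", call. = FALSE)
  E <- net$n_edges
  if (is.null(sd_range)) sd_range <- c(1, 10) / E
  n <- length(net$nodes)
  idx <- edge_index(n)
  ev <- edge_vector(net$weights, idx)
  pis <- with_seed(seed, vapply(seq_len(n_real), function(r) {
    sd_r <- stats::runif(1L, sd_range[1L], sd_range[2L])
    ev_r <- ev + stats::rnorm(E, sd = sd_r)
    percolate(noisy_network(net, ev_r, idx), cfg)$pi
  }, numeric(1)))
  new_robustness(pis, "noise",
                 list(n_real = n_real, sd_range = sd_range, config = cfg),
                 seed)
}

# Clone a network with replaced edge vector, bypassing the [-1, 1] check
# (noise may push weights slightly outside the correlation range).
noisy_network <- function(net, ev, idx) {
  w <- edge_matrix(ev, length(net$nodes), idx)
  dimnames(w) <- dimnames(net$weights)
  out <- net
  out$weights <- w
  out
}

# One shuffling iteration: select round(frac * E) distinct edges, randomly
# pair them, swap weights within each pair (odd leftover untouched). Returns
# the new weight vector and the selected edge indices. Shared by
# shuffle_robustness() and shuffle_coverage() so coverage estimates replay
# the exact selection procedure.
shuffle_once <- function(ev, frac) {
  E <- length(ev)
  m <- round(frac * E)
  sel <- sample.int(E, m)
  perm <- sample(sel)
  n_pair <- m %/% 2L
  if (n_pair > 0L) {
    a <- perm[seq_len(n_pair)]
    b <- perm[n_pair + seq_len(n_pair)]
    tmp <- ev[a]
    ev[a] <- ev[b]
    ev[b] <- tmp
  }
  list(ev = ev, selected = sel)
}

#' Percolation robustness under link shuffling
#'
#' Tests whether the percolation integral is driven by network structure
#' rather than by which weight sits on which edge. In each iteration a
#' fraction \code{frac} of the edges is selected without replacement,
#' randomly paired, and the weights within each pair are exchanged (the
#' weight multiset is preserved exactly); shuffles accumulate across
#' iterations and the PI is computed after each one. At the defaults (20
#' iterations, 80\% of edges) every edge is selected at least once with
#' probability \eqn{1 - 0.2^{20} \approx 1}.
#'
#' @param net a \code{"semantic_network"}.
#' @param cfg a [percolation_config()].
#' @param n_iter number of shuffling iterations.
#' @param frac fraction of edges selected per iteration, in (0, 1].
#' @param seed integer seed.
#' @return A \code{"robustness"} with \code{mode = "shuffle"}: the PI after
#'   each iteration, their mean, and \code{touched} (logical per edge:
#'   selected in at least one iteration).
#' @export
shuffle_robustness <- function(net, cfg = percolation_config(), n_iter = 20L,
                               frac = 0.8, seed = 1L) {
  stopifnot(inherits(net, "semantic_network"))
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("'n_iter' must be >= 1", call. = FALSE)
  if (!(frac > 0 && frac <= 1)) stop("'frac' must be in (0, 1]", call. = FALSE)
  if (net$n_edges < 2L) stop("need at least 2 edges to shuffle", call. = FALSE)
  n <- length(net$nodes)
  idx <- edge_index(n)
  ev <- edge_vector(net$weights, idx)
  touched <- logical(net$n_edges)
  pis <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      sh <- shuffle_once(ev, frac)
      ev <- sh$ev
      touched[sh$selected] <- TRUE
      pis[it] <- percolate(noisy_network(net, ev, idx), cfg)$pi
    }
  })
  out <- new_robustness(pis, "shuffle",
                        list(n_iter = n_iter, frac = frac, config = cfg),
                        seed, touched = touched)
  out$final_weights <- ev
  out
}

#' Monte-Carlo estimate of per-edge shuffle coverage
#'
#' Estimates, for every edge of an \code{n_edges}-edge network, the
#' probability of being selected at least once across \code{n_iter}
#' link-shuffling iterations that each select a fraction \code{frac} of the
#' edges without replacement. Replays the exact selection-and-swap procedure
#' of [shuffle_robustness()] (percolation itself does not influence which
#' edges are selected, so it is not run). The analytic value is
#' \eqn{1 - (1 - frac)^{n\_iter}} per edge.
#'
#' @param n_edges number of edges.
#' @param n_iter shuffling iterations per run.
#' @param frac fraction of edges selected per iteration.
#' @param n_runs number of independent seeded runs.
#' @param seed integer seed.
#' @return A list with \code{prob} (per-edge touch-probability estimates),
#'   \code{min_prob}, and the settings.
#' @export
shuffle_coverage <- function(n_edges = 100L, n_iter = 20L, frac = 0.8,
                             n_runs = 1000L, seed = 1L) {
  n_edges <- as.integer(n_edges)
  if (!(frac > 0 && frac <= 1)) stop("'frac' must be in (0, 1]", call. = FALSE)
  if (n_edges < 2L) stop("'n_edges' must be >= 2", call. = FALSE)
  hits <- integer(n_edges)
  ev0 <- numeric(n_edges)
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      touched <- logical(n_edges)
      ev <- ev0
      for (it in seq_len(n_iter)) {
        sh <- shuffle_once(ev, frac)
        ev <- sh$ev
        touched[sh$selected] <- TRUE
      }
      hits <- hits + touched
    }
  })
  prob <- hits / n_runs
  list(prob = prob, min_prob = min(prob),
       n_edges = n_edges, n_iter = n_iter, frac = frac, n_runs = n_runs,
       seed = seed)
}

#' Percolation integral under token-count control
#'
#' Creative-writing samples differ in length, and longer texts build larger
#' networks with mechanically larger percolation integrals. This harness
#' subsamples the token stream (without replacement, order preserved) to a
#' common target length, rebuilds the network and recomputes the PI,
#' averaging over repeated subsamples.
#'
#' @param tokens a \code{"token_sequence"}.
#' @param lexicon an \code{"embedding_lexicon"}.
#' @param target_length number of tokens to retain per subsample.
#' @param n_rep number of subsampling repetitions.
#' @param seed integer seed.
#' @param cfg a [percolation_config()].
#' @return A list with \code{pi_mean}, the per-repetition \code{pi_values},
#'   and the settings.
#' @export
pi_subsampled <- function(tokens, lexicon, target_length, n_rep = 20L,
                          seed = 1L, cfg = percolation_config()) {
  stopifnot(inherits(tokens, "token_sequence"))
  n <- length(tokens$tokens)
  target_length <- as.integer(target_length)
  if (target_length > n)
    stop("'target_length' exceeds the token count (", n, ")", call. = FALSE)
  pis <- with_seed(seed, vapply(seq_len(n_rep), function(r) {
    keep <- sort(sample.int(n, target_length))
    sub <- token_sequence(tokens$tokens[keep], source_id = tokens$source_id,
                          condition = tokens$condition)
    percolate(build_semantic_network(sub, lexicon), cfg)$pi
  }, numeric(1)))
  list(pi_mean = mean(pis), pi_values = pis, target_length = target_length,
       n_rep = n_rep, seed = seed)
}
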