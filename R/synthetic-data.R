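# Seeded generators for every input the pipeline consumes: cluster-structured
# embedding lexicons, token streams, multi-subject region-by-time BOLD
# matrices with planted block covariance, and mediation-structured behavioral
# tables. Each generator carries its ground truth so downstream recovery can
# be asserted.

#' Specification for a synthetic embedding lexicon
#'
#' Describes a lexicon of \code{n_clusters * words_per_cluster} tokens whose
#' vectors sit near orthonormal cluster means: tokens in the same cluster are
#' nearly parallel, tokens in different clusters nearly orthogonal. The
#' cluster separation makes semantic distances between clusters large and
#' within clusters small, which is the property all text-metric tests lean on.
#'
#' @param n_clusters number of semantic clusters (>= 1).
#' @param words_per_cluster tokens per cluster (>= 2).
#' @param dim embedding dimension (>= 2 and >= \code{n_clusters}, so that
#'   orthonormal cluster means exist).
#' @param within_noise_sd standard deviation of the isotropic Gaussian
#'   perturbation applied to each token vector before renormalization;
#'   0 collapses every cluster onto its mean.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return A list of class \code{"lexicon_spec"}.
#' @seealso [make_lexicon()]
#' @export
lexicon_spec <- function(n_clusters, words_per_cluster, dim,
                         within_noise_sd = 0.05, seed = 1L) {
  n_clusters <- as.integer(n_clusters)
  words_per_cluster <- as.integer(words_per_cluster)
  dim <- as.integer(dim)
  if (n_clusters < 1L) stop("'n_clusters' must be >= 1", call. = FALSE)
  if (words_per_cluster < 2L) stop("'words_per_cluster' must be >= 2",
                                   call. = FALSE)
  if (dim < 2L) stop("'dim' must be >= 2", call. = FALSE)
  if (dim < n_clusters)
    stop("'dim' (", dim, ") must be >= 'n_clusters' (", n_clusters,
         "): orthonormal cluster means cannot exist otherwise", call. = FALSE)
  if (within_noise_sd < 0) stop("'within_noise_sd' must be >= 0", call. = FALSE)
  structure(list(n_clusters = n_clusters,
                 words_per_cluster = words_per_cluster,
                 dim = dim, within_noise_sd = within_noise_sd,
                 seed = as.integer(seed)),
            class = "lexicon_spec")
}

#' Generate a cluster-structured embedding lexicon
#'
#' Draws orthonormal cluster means (the Q factor of a random Gaussian
#' matrix), perturbs each token vector with isotropic Gaussian noise of the
#' requested standard deviation, and renormalizes every vector to unit L2
#' norm. Tokens are named \code{c<cluster>_w<index>} so that tokenization is
#' trivially reversible in tests.
#'
#' @param spec a [lexicon_spec()].
#' @return An \code{"embedding_lexicon"}: a vocab x dim numeric matrix with
#'   token rownames and an integer \code{cluster} attribute giving each
#'   token's cluster.
#' @examples
#' lex <- make_lexicon(lexicon_spec(2, 3, dim = 8, within_noise_sd = 0.05))
#' dim(lex)
#' @export
make_lexicon <- function(spec) {
  stopifnot(inherits(spec, "lexicon_spec"))
  with_seed(spec$seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(spec$dim * spec$dim), spec$dim)))
    means <- t(q[, seq_len(spec$n_clusters), drop = FALSE])  # clusters x dim
    cluster <- rep(seq_len(spec$n_clusters), each = spec$words_per_cluster)
    vecs <- means[cluster, , drop = FALSE]
    if (spec$within_noise_sd > 0)
      vecs <- vecs + matrix(stats::rnorm(length(vecs), sd = spec$within_noise_sd),
                            nrow(vecs))
    vecs <- vecs / sqrt(rowSums(vecs^2))
    rownames(vecs) <- paste0("c", cluster, "_w",
                             sequence(rep(spec$words_per_cluster,
                                          spec$n_clusters)))
    structure(vecs, cluster = cluster, class = c("embedding_lexicon", "matrix"))
  })
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cl <- attr(x, "cluster")
  cat("Embedding lexicon: ", nrow(x), " tokens, dim ", ncol(x), sep = "")
  if (!is.null(cl)) cat(", ", length(unique(cl)), " clusters", sep = "")
  cat("\n")
  invisible(x)
}

#' Sample a synthetic story from a lexicon
#'
#' Tokens are drawn cluster-first (multinomial over \code{cluster_weights})
#' and then uniformly within the chosen cluster, producing a token stream
#' whose semantic trajectory is controlled by the weights: one-hot weights
#' give a semantically uniform story, spread weights a story that wanders
#' between clusters.
#'
#' @param lexicon an \code{"embedding_lexicon"} produced by [make_lexicon()].
#' @param n_tokens number of tokens to draw (>= 2).
#' @param cluster_weights probability vector over clusters (must sum to 1 and
#'   match the lexicon's cluster count).
#' @param seed integer seed.
#' @param source_id,condition optional identifiers carried on the result.
#' @return A \code{"token_sequence"}.
#' @export
make_story <- function(lexicon, n_tokens, cluster_weights, seed = 1L,
                       source_id = NA_character_, condition = NA_character_) {
  stopifnot(inherits(lexicon, "embedding_lexicon"))
  n_tokens <- as.integer(n_tokens)
  if (is.na(n_tokens) || n_tokens < 2L)
    stop("'n_tokens' must be >= 2", call. = FALSE)
  cl <- attr(lexicon, "cluster")
  n_clusters <- length(unique(cl))
  if (length(cluster_weights) != n_clusters)
    stop("'cluster_weights' has length ", length(cluster_weights),
         " but the lexicon has ", n_clusters, " clusters", call. = FALSE)
  if (abs(sum(cluster_weights) - 1) > 1e-8)
    stop("'cluster_weights' must sum to 1", call. = FALSE)
  with_seed(seed, {
    draw_cl <- sample.int(n_clusters, n_tokens, replace = TRUE,
                          prob = cluster_weights)
    tokens <- vapply(draw_cl, function(c) {
      members <- rownames(lexicon)[cl == c]
      members[sample.int(length(members), 1L)]
    }, character(1))
    token_sequence(tokens, source_id = source_id, condition = condition)
  })
}

#' Specification for synthetic parcellated BOLD data
#'
#' Defines multi-subject, multi-trial region-by-time series with planted
#' node-block covariance: every node belongs to one latent block per
#' condition, and its signal is the block's shared latent time course plus
#' independent Gaussian noise. Unordered block-pair identity then induces a
#' ground-truth partition of the \code{n_nodes(n_nodes-1)/2} edges into
#' \code{n_blocks(n_blocks+1)/2} edge communities, recoverable by the
#' edge-clustering stage. The two conditions use different node-to-block
#' assignments so condition-specific edge structure exists.
#'
#' @param n_nodes number of regions (>= 3).
#' @param n_networks number of atlas networks the nodes are partitioned into.
#' @param network_sizes integer partition of \code{n_nodes} over networks;
#'   defaults to a near-equal split.
#' @param n_blocks number of latent covariance blocks (<= n_nodes).
#' @param T_trial time points per trial (>= 2).
#' @param n_trials trials per subject and condition.
#' @param n_subjects number of subjects.
#' @param noise_sd node-level noise standard deviation (the latent block
#'   signals are standard normal over time).
#' @param seed integer seed.
#' @return A list of class \code{"bold_spec"}.
#' @export
bold_spec <- function(n_nodes, n_networks = 2L, network_sizes = NULL,
                      n_blocks = 2L, T_trial = 100L, n_trials = 2L,
                      n_subjects = 1L, noise_sd = 0.1, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_blocks <- as.integer(n_blocks)
  T_trial <- as.integer(T_trial)
  if (n_nodes < 3L) stop("'n_nodes' must be >= 3", call. = FALSE)
  if (T_trial < 2L) stop("'T_trial' must be >= 2", call. = FALSE)
  if (n_blocks < 1L || n_blocks > n_nodes)
    stop("'n_blocks' must be in [1, n_nodes]", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (is.null(network_sizes)) {
    base <- n_nodes %/% n_networks
    network_sizes <- rep(base, n_networks)
    network_sizes[seq_len(n_nodes - base * n_networks)] <-
      network_sizes[seq_len(n_nodes - base * n_networks)] + 1L
  }
  network_sizes <- as.integer(network_sizes)
  if (sum(network_sizes) != n_nodes)
    stop("'network_sizes' must sum to 'n_nodes'", call. = FALSE)
  structure(list(n_nodes = n_nodes, n_networks = as.integer(n_networks),
                 network_sizes = network_sizes, n_blocks = n_blocks,
                 T_trial = T_trial, n_trials = as.integer(n_trials),
                 n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bold_spec")
}

# Contiguous near-equal block assignment of n nodes into b blocks.
block_assignment <- function(n, b) {
  sizes <- rep(n %/% b, b)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(b), times = sizes)
}

#' Generate synthetic BOLD region time series with planted edge communities
#'
#' For each subject, condition and trial, draws \code{n_blocks} independent
#' standard-normal latent time courses, assigns each node to one block, and
#' sets the node signal to its block latent plus independent
#' \code{N(0, noise_sd^2)} noise. Condition \code{"A"} uses a contiguous
#' block assignment; condition \code{"B"} uses a cyclic shift of it, so the
#' two conditions carry different edge structure.
#'
#' @param spec a [bold_spec()].
#' @return A list of class \code{"bold_set"} with elements \code{series}
#'   (nested list: subject, then condition \code{"A"}/\code{"B"}, then trial,
#'   each a [region_ts()]), \code{atlas} (data.frame with \code{node} and
#'   \code{network}), \code{blocks} (per-condition node-to-block
#'   assignments), and \code{spec}.
#' @seealso [edge_ground_truth()] for the induced edge-community labels.
#' @export
make_bold <- function(spec) {
  stopifnot(inherits(spec, "bold_spec"))
  atlas <- data.frame(
    node = seq_len(spec$n_nodes),
    network = rep(paste0("net", seq_len(spec$n_networks)),
                  times = spec$network_sizes),
    stringsAsFactors = FALSE)
  blocks_a <- block_assignment(spec$n_nodes, spec$n_blocks)
  shift <- max(1L, spec$n_nodes %/% (2L * spec$n_blocks))
  blocks_b <- blocks_a[((seq_len(spec$n_nodes) + shift - 1L) %% spec$n_nodes) + 1L]
  blocks <- list(A = blocks_a, B = blocks_b)
  series <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      stats::setNames(lapply(names(blocks), function(cond) {
        bl <- blocks[[cond]]
        lapply(seq_len(spec$n_trials), function(tr) {
          latent <- matrix(stats::rnorm(spec$n_blocks * spec$T_trial),
                           spec$n_blocks, spec$T_trial)
          x <- latent[bl, , drop = FALSE]
          if (spec$noise_sd > 0)
            x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd),
                            nrow(x))
          region_ts(x, atlas = atlas$network, subject = s,
                    condition = cond, trial = tr)
        })
      }), names(blocks))
    })
  })
  structure(list(series = series, atlas = atlas, blocks = blocks, spec = spec),
            class = "bold_set")
}

#' Ground-truth edge-community labels from a block assignment
#'
#' Each edge (i, j) inherits the identity of the unordered block pair of its
#' endpoints, giving \code{b(b+1)/2} possible edge communities for \code{b}
#' blocks (within-block pairs included). These labels are the planted truth
#' that [cluster_edges()] should recover on [make_bold()] output.
#'
#' @param blocks integer node-to-block assignment vector.
#' @return Integer vector of length \code{n(n-1)/2} in [edge_index()] order,
#'   with labels renumbered consecutively from 1 in order of appearance.
#' @export
edge_ground_truth <- function(blocks) {
  n <- length(blocks)
  idx <- edge_index(n)
  bi <- pmin(blocks[idx[, 1L]], blocks[idx[, 2L]])
  bj <- pmax(blocks[idx[, 1L]], blocks[idx[, 2L]])
  key <- paste(bi, bj, sep = "-")
  as.integer(factor(key, levels = unique(key)))
}

#' Specification for a mediation-structured behavioral table
#'
#' @param n sample size (>= 10).
#' @param a_path effect of x on the mediator m.
#' @param b_path effect of m on y, holding x fixed.
#' @param c_prime direct effect of x on y.
#' @param noise_sd standard deviation of the Gaussian disturbances on m and y.
#' @param seed integer seed.
#' @return A list of class \code{"mediation_spec"}.
#' @export
mediation_spec <- function(n, a_path, b_path, c_prime = 0,
                           noise_sd = 1, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop("'n' must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(n = n, a_path = a_path, b_path = b_path, c_prime = c_prime,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mediation_spec")
}

#' Generate a three-variable mediation table
#'
#' Simulates the standard single-mediator path model: \code{x ~ N(0, 1)},
#' \code{m = a x + e_m}, \code{y = c' x + b m + e_y} with independent
#' Gaussian disturbances. The population indirect effect is \code{a * b} on
#' the unstandardized scale.
#'
#' @param spec a [mediation_spec()].
#' @return A data.frame with columns \code{x}, \code{m}, \code{y}.
#' @seealso [mediate()]
#' @export
make_mediation_table <- function(spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  with_seed(spec$seed, {
    x <- stats::rnorm(spec$n)
    m <- spec$a_path * x + stats::rnorm(spec$n, sd = spec$noise_sd)
    y <- spec$c_prime * x + spec$b_path * m +
      stats::rnorm(spec$n, sd = spec$noise_sd)
    data.frame(x = x, m = m, y = y)
  })
}
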