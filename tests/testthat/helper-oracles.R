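# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: components come from boolean matrix-power closure
# (not igraph), pairwise scores from explicit double loops.

# Giant-component size among non-isolated nodes, by transitive closure of
# the boolean adjacency matrix.
oracle_gc <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  if (all(deg == 0)) return(0L)
  reach <- adj | diag(TRUE, n)
  for (step in seq_len(n)) {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1L, function(r) paste(which(r), collapse = ","))
  keep <- deg > 0
  max(table(comp[keep]))
}

# Percolation integral by full rebuild at every threshold, no shortcuts
# beyond the stopping rule itself (which is part of the definition).
oracle_percolate <- function(weights, start_th = 0, end_th = 1,
                             th_res = 0.0125, gc_min = 3) {
  n <- nrow(weights)
  grid <- start_th + th_res * (0:round((end_th - start_th) / th_res))
  total <- 0
  gc_trace <- integer(0)
  for (th in grid) {
    adj <- weights >= th - 1e-12
    diag(adj) <- FALSE
    gc <- oracle_gc(adj)
    gc_trace <- c(gc_trace, gc)
    if (gc < gc_min) break
    total <- total + gc * th_res
  }
  list(pi = total, gc_trace = gc_trace)
}

# Mean pairwise cosine distance by explicit double loop.
oracle_pairwise_mean_dist <- function(mats) {
  dists <- c()
  for (m in mats) {
    nt <- nrow(m)
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        cs <- sum(m[i, ] * m[j, ]) /
          (sqrt(sum(m[i, ]^2)) * sqrt(sum(m[j, ]^2)))
        dists <- c(dists, 1 - cs)
      }
    }
  }
  mean(dists)
}

# Random symmetric weight matrix with entries in [-1, 1].
random_weights <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, -1, 1)
  w <- w + t(w)
  diag(w) <- 1
  w
}

# A small two-cluster lexicon shared by several text/network tests.
fixture_lexicon <- function(n_clusters = 2, words = 5, dim = 10, sd = 0.05,
                            seed = 11) {
  make_lexicon(lexicon_spec(n_clusters, words, dim = dim,
                            within_noise_sd = sd, seed = seed))
}
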