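# Edge co-fluctuation construction, edge-community detection, and the
# node-level overlap (entropy) and similarity maps.

test_that("zscore standardizes with the population SD and is idempotent", {
  m <- rbind(c(1, 2, 3, 4), c(0, 0, 1, 1), c(-2, 5, 0, 3))
  z <- zscore(region_ts(m))
  for (i in 1:3) {
    mu <- mean(m[i, ]); sd_pop <- sqrt(mean((m[i, ] - mu)^2))
    expect_equal(z$mat[i, ], (m[i, ] - mu) / sd_pop, tolerance = 1e-12)
  }
  expect_equal(zscore(z)$mat, z$mat, tolerance = 1e-12)
  # location invariance
  expect_equal(zscore(region_ts(m + 100))$mat, z$mat, tolerance = 1e-12)
  expect_error(zscore(region_ts(rbind(m, 7))), "zero-variance.*4")
})

test_that("trial concatenation joins z-scored trials in order", {
  set.seed(51)
  trials <- lapply(1:10, function(i)
    region_ts(matrix(rnorm(4 * 30), 4), trial = i))
  cat10 <- concatenate_trials(trials)
  expect_identical(ncol(cat10$mat), 300L)
  expect_true(cat10$z_scored)
  expect_equal(concatenate_trials(trials[1])$mat, zscore(trials[[1]])$mat)

  # re-z-scoring the concatenation changes values iff trial means differ
  # after standardization... construct trials whose z-scored parts have
  # equal means (always 0) but different variances cannot arise; instead
  # check that per-trial z-scoring differs from whole-series z-scoring when
  # trial means differ
  a <- matrix(rnorm(4 * 30), 4)
  b <- matrix(rnorm(4 * 30), 4) + 5
  per_trial <- concatenate_trials(list(region_ts(a), region_ts(b)))
  whole <- zscore(region_ts(cbind(a, b)))
  expect_gt(max(abs(per_trial$mat - whole$mat)), 0.1)

  expect_error(concatenate_trials(list(region_ts(matrix(rnorm(12), 3)),
                                       region_ts(matrix(rnorm(16), 4)))),
               "region count")
})

test_that("condition difference is elementwise and resets the z flag", {
  a <- region_ts(matrix(1:12, 3), condition = "A")
  b <- region_ts(matrix(rep(c(1, 0, 2, 1), 3), 3, byrow = TRUE),
                 condition = "B")
  d <- condition_difference(a, b)
  expect_equal(d$mat, a$mat - b$mat)
  expect_false(d$z_scored)
  expect_equal(condition_difference(a, a)$mat, matrix(0, 3, 4))
  expect_error(condition_difference(a, region_ts(matrix(1:15, 3))),
               "shape mismatch")
})

test_that("edge series are pointwise products whose means are Pearson r", {
  set.seed(53)
  z <- zscore(region_ts(matrix(rnorm(4 * 6), 4)))
  ets <- edge_time_series(z)
  expect_identical(nrow(ets$mat), 6L)
  # explicit double loop oracle
  e <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    e <- e + 1
    expect_equal(ets$mat[e, ], z$mat[i, ] * z$mat[j, ], tolerance = 1e-12)
    r_pop <- mean(z$mat[i, ] * z$mat[j, ])  # divisor-T Pearson on z-scores
    expect_equal(mean(ets$mat[e, ]), r_pop, tolerance = 1e-12)
    expect_equal(r_pop, cor(z$mat[i, ], z$mat[j, ]), tolerance = 1e-10)
  }

  # identical and sign-flipped pairs
  base <- matrix(rnorm(3 * 8), 3)
  base[2, ] <- base[1, ]
  base[3, ] <- -base[1, ]
  zz <- zscore(region_ts(base))
  m <- edge_time_series(zz)$mat
  expect_equal(mean(m[1, ]), 1, tolerance = 1e-12)   # edge (1,2)
  expect_equal(mean(m[2, ]), -1, tolerance = 1e-12)  # edge (1,3)

  expect_error(edge_time_series(region_ts(matrix(rnorm(12), 3))),
               "z-scored")
})

test_that("edge-series time means equal pairwise Pearson r on random fixtures", {
  set.seed(59)
  for (rep in 1:25) {
    n <- sample(3:8, 1); tt <- sample(5:40, 1)
    z <- zscore(region_ts(matrix(rnorm(n * tt), n)))
    ets <- edge_time_series(z)
    r <- cor(t(z$mat))
    expect_equal(rowMeans(ets$mat), r[cbind(ets$index[, 1], ets$index[, 2])],
                 tolerance = 1e-10)
  }
})

test_that("group averaging is the elementwise mean across subjects", {
  set.seed(61)
  mk <- function() edge_time_series(zscore(region_ts(matrix(rnorm(4 * 10), 4))))
  e1 <- mk(); e2 <- mk(); e3 <- mk()
  avg <- group_average(list(e1, e2, e3))
  expect_equal(avg$mat, (e1$mat + e2$mat + e3$mat) / 3, tolerance = 1e-12)
  expect_identical(avg$provenance, "group-average")
  expect_equal(group_average(list(e1))$mat, e1$mat)

  neg <- e1; neg$mat <- -e1$mat
  expect_equal(group_average(list(e1, neg))$mat, matrix(0, 6, 10))

  short <- edge_time_series(zscore(region_ts(matrix(rnorm(4 * 8), 4))))
  expect_error(group_average(list(e1, short)), "per-subject T")
})

test_that("edge functional connectivity matches the brute-force formula", {
  set.seed(67)
  z <- zscore(region_ts(matrix(rnorm(4 * 6), 4)))
  ets <- edge_time_series(z)
  fc <- edge_fc(ets, "inner-product")
  for (e in 1:6) for (f in 1:6) {
    expected <- sum(ets$mat[e, ] * ets$mat[f, ]) /
      sqrt(sum(ets$mat[e, ]^2) * sum(ets$mat[f, ]^2))
    if (e == f) expected <- 1
    expect_equal(fc$mat[e, f], expected, tolerance = 1e-12)
  }
  expect_equal(fc$mat, t(fc$mat))

  fcp <- edge_fc(ets, "pearson")
  expect_equal(fcp$mat[1, 2], cor(ets$mat[1, ], ets$mat[2, ]),
               tolerance = 1e-12)

  # orthogonal rows score 0 in inner-product mode; zero rows warn
  ortho <- ets
  ortho$mat <- rbind(c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0),
                     matrix(rnorm(4 * 6), 4))
  expect_equal(edge_fc(ortho, "inner-product")$mat[1, 2], 0)
  zero <- ets
  zero$mat[2, ] <- 0
  expect_warning(fc0 <- edge_fc(zero, "inner-product"), "zero-norm")
  expect_equal(fc0$mat[2, 3], 0)
})

test_that("k-means recovers planted edge communities and is seeded", {
  b <- make_bold(bold_spec(n_nodes = 16, n_blocks = 2, T_trial = 300,
                           n_trials = 1, noise_sd = 0.1, seed = 71))
  z <- b$series[[1]]$A[[1]]  # already built from z-scored latents
  ets <- edge_time_series(zscore(z))
  gt <- edge_ground_truth(b$blocks$A)
  k_true <- length(unique(gt))
  cl <- cluster_edges(ets, k_range = k_true, restarts = 10, seed = 5)
  ari <- mclust::adjustedRandIndex(cl$labels[[1]], gt)
  expect_gte(ari, 0.9)

  cl2 <- cluster_edges(ets, k_range = k_true, restarts = 10, seed = 5)
  expect_identical(cl$labels, cl2$labels)
})

test_that("degenerate identical edge rows collapse to one community", {
  ets <- structure(list(mat = matrix(1, 6, 10), index = edge_index(4),
                        n_nodes = 4L, atlas = NULL, provenance = NULL),
                   class = "edge_ts")
  expect_message(cl <- cluster_edges(ets, k_range = 3, seed = 1),
                 "distinct edge rows")
  expect_identical(unique(cl$labels[[1]]), 1L)
})

test_that("node community matrix mirrors edge labels symmetrically", {
  x <- node_community_matrix(c(1L, 2L, 2L), k = 2)
  expect_identical(x[2, 1], 1L)  # edge (1,2)
  expect_identical(x[3, 1], 2L)  # edge (1,3)
  expect_identical(x[3, 2], 2L)  # edge (2,3)
  expect_true(is.na(x[1, 1]) && is.na(x[2, 2]) && is.na(x[3, 3]))
  expect_identical(x[upper.tri(x)], t(x)[upper.tri(x)])

  all_one <- node_community_matrix(rep(1L, 6), k = 3)
  expect_true(all(all_one[!is.na(all_one)] == 1L))
})

test_that("normalized entropy hits its boundary cases and hand value", {
  one <- node_community_matrix(rep(1L, 6), k = 3)
  expect_equal(overlap_entropy(one), rep(0, 4), tolerance = 1e-12)

  # node 1 of a 5-node matrix with edges labeled 1,1,2,2: exact uniform
  labs <- c(1L, 1L, 2L, 2L, 1L, 2L, 2L, 1L, 1L, 2L)
  x5 <- node_community_matrix(labs, k = 2)
  expect_equal(overlap_entropy(x5)[1], 1, tolerance = 1e-12)

  # counts (3, 1) at k = 2
  x41 <- node_community_matrix(c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
                               k = 2)
  expect_equal(overlap_entropy(x41)[1],
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  expect_equal(overlap_entropy(x41)[1], 0.8112781, tolerance = 1e-6)

  expect_error(overlap_entropy(x41, k = 1), "k")
})

test_that("community similarity counts agreements over shared positions", {
  # hand-built 5-node label matrix
  labs <- c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 2L)
  x <- node_community_matrix(labs, k = 2)
  s <- community_similarity(x)$similarity
  # s_12 compares positions {3, 4, 5}: x[3,1]=1 vs x[3,2]=1 (agree),
  # x[4,1]=2 vs x[4,2]=2 (agree), x[5,1]=2 vs x[5,2]=2 (agree)
  manual <- mean(c(x[3, 1] == x[3, 2], x[4, 1] == x[4, 2],
                   x[5, 1] == x[5, 2]))
  expect_equal(s[1, 2], manual, tolerance = 1e-12)

  # identical columns give similarity 1
  same <- node_community_matrix(rep(2L, 10), k = 2)
  expect_equal(community_similarity(same)$similarity[1, 2], 1)

  # columns disagreeing at every comparable position give 0
  y <- matrix(NA_integer_, 4, 4)
  y[cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))] <- c(9L, 1L, 1L, 2L, 2L, 9L)
  y[lower.tri(y)] <- t(y)[lower.tri(y)]
  expect_equal(community_similarity(y)$similarity[1, 2], 0)

  # per-node within-network means; single-node networks are NA
  atlas <- c("p", "p", "q", "q", "r")
  cs <- community_similarity(x, atlas = atlas)
  expect_equal(cs$node_mean[1], s[1, 2])
  expect_true(is.na(cs$node_mean[5]))
})

test_that("profiles average elementwise over the k range", {
  labs2 <- c(1L, 1L, 2L, 2L, 1L, 2L, 2L, 1L, 1L, 2L)
  labs3 <- c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L, 1L)
  comm <- structure(list(labels = list(k2 = labs2, k3 = labs3),
                         inertia = c(k2 = 0, k3 = 0), k_range = 2:3,
                         index = edge_index(5), n_nodes = 5L,
                         atlas = rep(c("p", "q"), c(3, 2)), seed = 1),
                    class = "edge_communities")
  p2 <- community_profile(comm, 2)
  p3 <- community_profile(comm, 3)
  avg <- average_over_k(list(p2, p3))
  expect_equal(avg$entropy, (p2$entropy + p3$entropy) / 2, tolerance = 1e-12)
  expect_equal(avg$similarity, (p2$similarity + p3$similarity) / 2,
               tolerance = 1e-12)
  expect_equal(average_over_k(list(p2))$entropy, p2$entropy)
  expect_equal(overlap_profiles(comm)$entropy, avg$entropy)
})

test_that("entropy and similarity stay in [0, 1] and permute under relabeling", {
  set.seed(73)
  for (k in c(2, 5, 9)) {
    labs <- sample.int(k, 45, replace = TRUE)
    x <- node_community_matrix(labs, k = k)
    ent <- overlap_entropy(x)
    sim <- community_similarity(x)$similarity
    expect_true(all(ent >= 0 & ent <= 1))
    expect_true(all(sim >= -1e-12 & sim <= 1 + 1e-12))

    perm <- sample(10)
    xp <- x[perm, perm]
    attr(xp, "k") <- k
    expect_equal(sort(overlap_entropy(xp, k)), sort(ent), tolerance = 1e-12)
  }
})

test_that("pipeline maps distinguish block-nested from block-straddling networks", {
  # blocks of unequal size; one atlas network nested in the large block,
  # one straddling the two smaller blocks
  blocks <- c(rep(1L, 12), rep(2L, 8), rep(3L, 4))
  set.seed(83)
  latent <- matrix(rnorm(3 * 300), 3)
  z <- zscore(region_ts(latent[blocks, ] +
                          matrix(rnorm(24 * 300, sd = 0.1), 24)))
  ets <- edge_time_series(z)
  gt <- edge_ground_truth(blocks)
  k_true <- length(unique(gt))
  cl <- cluster_edges(ets, k_range = k_true, seed = 7)
  expect_gte(mclust::adjustedRandIndex(cl$labels[[1]], gt), 0.9)

  x <- node_community_matrix(cl$labels[[1]], k = k_true)
  atlas <- rep("other", 24)
  atlas[17:20] <- "nested"    # inside block 2
  atlas[11:14] <- "straddle"  # spans blocks 1 and 2
  ent <- overlap_entropy(x, k = k_true)
  sim <- community_similarity(x, atlas = atlas)
  # nodes of a network nested in one block share a community profile, so
  # their within-network similarity exceeds the straddling network's, and
  # the straddling network spreads over more edge communities
  expect_gt(mean(sim$node_mean[atlas == "nested"]),
            mean(sim$node_mean[atlas == "straddle"]))
  expect_gt(mean(ent[atlas == "straddle"]), mean(ent[atlas == "nested"]))
})
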