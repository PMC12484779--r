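# The statistical battery: Spearman + BH, bootstrap mediation, t tests with
# effect sizes, Kruskal-Wallis with epsilon-squared, DSCF post hoc.

test_that("spearman_fdr ranks, correlates and BH-adjusts over the family", {
  tab <- data.frame(a = c(1, 2, 3, 4, 5, 6),
                    b = c(2, 4, 5, 7, 9, 12),      # strictly monotone with a
                    c = c(3.1, 1.2, 5.5, 2.2, 4.4, 0.7),
                    d = c(0.5, 2.5, 1.5, 4.5, 3.5, 6.5))
  res <- spearman_fdr(tab, list(c("a", "b"), c("a", "c"), c("a", "d")))
  expect_equal(res$rho[1], 1, tolerance = 1e-12)
  expect_equal(res$p[1], 0)

  # tie-free Spearman equals the classical rank-difference formula
  d2 <- sum((rank(tab$a) - rank(tab$c))^2)
  expect_equal(res$rho[2], 1 - 6 * d2 / (6 * 35), tolerance = 1e-12)

  # BH step-up on the family (0.01, 0.02, 0.04) -> (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  # monotone, and never below raw
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_identical(order(res$p), order(res$p_adj))

  expect_error(spearman_fdr(data.frame(a = rep(1, 5), b = 1:5),
                            list(c("a", "b"))), "constant")
})

test_that("partial spearman on rank residuals removes a rank-linear covariate", {
  set.seed(91)
  n <- 60
  cov <- rnorm(n)
  x <- cov + rnorm(n, sd = 0.3)
  y <- cov + rnorm(n, sd = 0.3)
  tab <- data.frame(x = x, y = y, cov = cov)
  plain <- spearman_fdr(tab, list(c("x", "y")))
  partial <- spearman_fdr(tab, list(c("x", "y")), covariates = "cov")
  expect_gt(plain$rho, 0.6)
  expect_lt(abs(partial$rho), 0.3)
})

test_that("mediation satisfies the OLS additive identity on any input", {
  set.seed(93)
  for (rep in 1:5) {
    x <- rnorm(40); m <- 0.3 * x + rnorm(40); y <- 0.2 * x + 0.5 * m + rnorm(40)
    fit <- mediate(x, m, y, n_boot = 50, seed = rep)
    expect_equal(fit$total, fit$direct + fit$indirect, tolerance = 1e-10)
    expect_lte(fit$ci_low, fit$ci_high)
  }
  expect_error(mediate(1:20, 2 * (1:20), rnorm(20)), "collinear")
})

test_that("mediation recovers planted paths and nulls", {
  tab <- make_mediation_table(mediation_spec(5000, a_path = 0.5,
                                             b_path = 0.4, c_prime = 0.2,
                                             noise_sd = 1, seed = 95))
  fit <- mediate(tab$x, tab$m, tab$y, n_boot = 1000, seed = 2)
  expect_lt(abs(fit$indirect - 0.20), 0.05)

  null_tab <- make_mediation_table(mediation_spec(2000, a_path = 0.5,
                                                  b_path = 0, seed = 97))
  null_fit <- mediate(null_tab$x, null_tab$m, null_tab$y, n_boot = 500,
                      seed = 3)
  expect_lte(null_fit$ci_low, 0)
  expect_gte(null_fit$ci_high, 0)
})

test_that("bootstrap CI covers the population indirect effect at ~95%", {
  # population standardized indirect effect for a=0.5, b=0.4, sd=1:
  # a*b / sd(y) with sd(y) = sqrt((c' + ab)^2 + b^2 + 1)
  a <- 0.5; b <- 0.4
  truth <- a * b / sqrt((a * b)^2 + b^2 + 1)
  hits <- 0L
  for (s in 1:200) {
    tab <- make_mediation_table(mediation_spec(200, a, b, noise_sd = 1,
                                               seed = 1000 + s))
    fit <- mediate(tab$x, tab$m, tab$y, n_boot = 400, seed = s)
    if (fit$ci_low <= truth && truth <= fit$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
  expect_lte(hits / 200, 0.99)
})

test_that("paired t carries the d = t / sqrt(n) identity", {
  a <- c(4.1, 5.2, 3.3, 6.4, 5.0)
  b <- c(3.9, 4.8, 3.6, 5.1, 4.2)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$effect, res$statistic / sqrt(5), tolerance = 1e-12)

  # zero-mean nonzero-variance differences give t = 0, d = 0
  sym <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(sym$statistic, 0, tolerance = 1e-12)
  expect_equal(sym$effect, 0, tolerance = 1e-12)

  expect_error(paired_t(a, a), "zero-variance")
  set.seed(99)
  for (rep in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    res <- paired_t(x, y)
    expect_equal(res$effect, res$statistic / sqrt(30), tolerance = 1e-12)
  }
})

test_that("one-sample t behaves at the null and on a hand-computed case", {
  v <- c(2, 4, 4, 6)
  expect_equal(one_sample_t(v, mu = 4)$statistic, 0, tolerance = 1e-12)
  res <- one_sample_t(v, mu = 0)
  expect_equal(res$statistic, 4 / (sd(v) / 2), tolerance = 1e-12)
  expect_error(one_sample_t(c(1, 2), mu = 0), "at least 3")
})

test_that("kruskal-wallis H, epsilon-squared and tie conventions", {
  # hand-ranked tie-free case
  g <- list(c(1.2, 3.4, 2.2), c(5.1, 4.4, 6.0), c(2.8, 3.1))
  res <- kruskal_wallis_eps2(g)
  r <- rank(unlist(g))
  Ri <- c(sum(r[1:3]), sum(r[4:6]), sum(r[7:8]))
  H_hand <- 12 / (8 * 9) * sum(Ri^2 / c(3, 3, 2)) - 3 * 9
  expect_equal(res$statistic, H_hand, tolerance = 1e-12)
  expect_equal(res$effect, H_hand / 7, tolerance = 1e-12)
  expect_equal(res$df, 2)

  # chi-square p is close to the exhaustive permutation reference
  perm_p <- local({
    pooled <- unlist(g)
    combs1 <- combn(8, 3)
    Hs <- numeric(0)
    for (c1 in seq_len(ncol(combs1))) {
      rest <- setdiff(1:8, combs1[, c1])
      combs2 <- combn(rest, 3)
      for (c2 in seq_len(ncol(combs2))) {
        lab <- integer(8)
        lab[combs1[, c1]] <- 1; lab[combs2[, c2]] <- 2; lab[lab == 0] <- 3
        Hs <- c(Hs, kruskal.test(pooled, factor(lab))$statistic)
      }
    }
    mean(Hs >= res$statistic - 1e-12)
  })
  expect_lt(abs(res$p - perm_p), 0.05)

  # all observations tied: H = 0 by convention
  tied <- kruskal_wallis_eps2(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$effect, 0)

  expect_error(kruskal_wallis_eps2(list(1:3, numeric(0))), "empty")
})

test_that("printed effect sizes recompute from printed statistics", {
  expect_equal(round(epsilon_squared(239, 400), 3), 0.599)
  expect_equal(round(cohens_d_from_t(2.514, 68), 3), 0.305)
})

test_that("dscf statistic matches the tie-corrected rank-sum z * sqrt(2)", {
  x <- c(1.5, 2.2, 3.1, 4.0, 2.5)
  y <- c(3.3, 4.1, 5.2, 4.8)
  z3 <- c(2.0, 2.9, 3.5)
  res <- dscf_posthoc(list(a = x, b = y, c = z3))
  w <- suppressWarnings(wilcox.test(y, x, correct = FALSE, exact = FALSE))
  zval <- qnorm(w$p.value / 2, lower.tail = FALSE) *
    sign(w$statistic - length(x) * length(y) / 2)
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_equal(ab$statistic, unname(zval) * sqrt(2), tolerance = 1e-10)

  # antisymmetry under swapping the pair
  swapped <- dscf_posthoc(list(b = y, a = x, c = z3))
  ba <- swapped[swapped$group1 == "b" & swapped$group2 == "a", ]
  expect_equal(ba$statistic, -ab$statistic, tolerance = 1e-12)
  expect_equal(ba$p, ab$p, tolerance = 1e-12)
})

test_that("dscf separates a shifted group and stays quiet under the null", {
  set.seed(101)
  null_ok <- 0L
  for (run in 1:100) {
    gs <- list(rnorm(30), rnorm(30), rnorm(30))
    if (min(dscf_posthoc(gs)$p) > 0.05) null_ok <- null_ok + 1L
  }
  expect_gte(null_ok / 100, 0.90)

  set.seed(103)
  gs <- list(rnorm(30), rnorm(30), rnorm(30) + 5)
  res <- dscf_posthoc(gs)
  shifted <- res[res$group2 == "g3" | res$group1 == "g3", ]
  expect_true(all(shifted$p < 0.001))
  other <- res[res$group1 != "g3" & res$group2 != "g3", ]
  expect_true(all(other$p > 0.05))

  expect_error(dscf_posthoc(list(1:3, 1:3)), "at least 3")
  expect_error(dscf_posthoc(list(1:3, 1:3, 2)), ">= 2")
})
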