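# The study-level statistical battery: Spearman correlations (optionally
# partial) with Benjamini-Hochberg FDR control, percentile-bootstrap
# mediation, paired and one-sample t tests with Cohen's d, Kruskal-Wallis
# with the epsilon-squared effect size, and Dwass-Steel-Critchlow-Fligner
# pairwise post hoc tests.

new_group_comparison <- function(method, statistic, df, p, effect,
                                 effect_type, n, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   effect = effect, effect_type = effect_type, n = n),
              extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.null(x$df)) paste0(", df = ", format(x$df, digits = 4)),
      ", p = ", format.pval(x$p, digits = 3),
      ", ", x$effect_type, " = ", format(x$effect, digits = 3), "\n",
      sep = "")
  invisible(x)
}

# Two-sided p for a Spearman rho via the t approximation on n - 2 - q df.
spearman_p <- function(rho, n, q = 0L) {
  df <- n - 2L - q
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tval), df)
}

#' Spearman correlations with FDR control
#'
#' Computes Spearman rank correlations (average ranks for ties) for a
#' declared family of variable pairs and applies Benjamini-Hochberg
#' adjustment over that family. With \code{covariates}, partial Spearman
#' correlations are computed by correlating the residuals of rank-on-rank
#' regressions of each variable on the covariates. P values use the t
#' approximation on \code{n - 2 - q} degrees of freedom (q covariates).
#'
#' @param table data.frame of numeric per-subject scores.
#' @param pairs list of length-2 character vectors (or a 2-column matrix)
#'   naming the variable pairs forming one FDR family.
#' @param covariates optional character vector of covariate column names.
#' @return A data.frame with columns \code{var1}, \code{var2}, \code{n},
#'   \code{rho}, \code{p}, \code{p_adj}.
#' @export
spearman_fdr <- function(table, pairs, covariates = NULL) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  res <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    cols <- c(pr, covariates)
    if (!all(cols %in% names(table)))
      stop("missing column(s): ",
           paste(setdiff(cols, names(table)), collapse = ", "), call. = FALSE)
    d <- table[stats::complete.cases(table[cols]), cols, drop = FALSE]
    n <- nrow(d)
    if (n < 4L)
      stop("fewer than 4 complete rows for pair ", pr[1L], " ~ ", pr[2L],
           call. = FALSE)
    for (cl in pr)
      if (length(unique(d[[cl]])) == 1L)
        stop("constant column: ", cl, call. = FALSE)
    rx <- rank(d[[pr[1L]]])
    ry <- rank(d[[pr[2L]]])
    q <- length(covariates)
    if (q > 0L) {
      rc <- vapply(covariates, function(cv) rank(d[[cv]]), numeric(n))
      rx <- stats::lm.fit(cbind(1, rc), rx)$residuals
      ry <- stats::lm.fit(cbind(1, rc), ry)$residuals
    }
    rho <- stats::cor(rx, ry)
    data.frame(var1 = pr[1L], var2 = pr[2L], n = n, rho = rho,
               p = spearman_p(rho, n, q), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Percentile-bootstrap mediation analysis
#'
#' Fits the standard single-mediator model on standardized variables:
#' \code{a} from \code{m ~ x}, \code{b} and the direct effect \code{c'} from
#' \code{y ~ x + m}; the indirect effect is \code{a * b} and the total
#' effect (from \code{y ~ x}) equals \code{c' + a * b} exactly by OLS
#' algebra. The confidence interval for the indirect effect is the 2.5th and
#' 97.5th percentile of case-resampled bootstrap replicates.
#'
#' @param x,m,y numeric vectors: predictor, mediator, outcome.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return A list of class \code{"mediation"} with standardized paths
#'   \code{a}, \code{b}, \code{direct}, \code{indirect}, \code{total},
#'   percentile bounds \code{ci_low}/\code{ci_high}, \code{boot}
#'   (replicates), \code{n}, \code{n_boot}, \code{seed}.
#' @examples
#' tab <- make_mediation_table(mediation_spec(200, 0.5, 0.4, seed = 3))
#' mediate(tab$x, tab$m, tab$y, n_boot = 200, seed = 3)
#' @export
mediate <- function(x, m, y, n_boot = 1000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n)
    stop("'x', 'm', 'y' must have equal length", call. = FALSE)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
  if (abs(stats::cor(x, m)) > 1 - 1e-10)
    stop("'x' and 'm' are collinear", call. = FALSE)
  zx <- as.numeric(scale(x)); zm <- as.numeric(scale(m))
  zy <- as.numeric(scale(y))
  paths <- function(i) {
    a <- stats::cov(zx[i], zm[i]) / stats::var(zx[i])
    fit <- stats::lm.fit(cbind(1, zx[i], zm[i]), zy[i])$coefficients
    c(a = a, b = unname(fit[3L]), c_prime = unname(fit[2L]))
  }
  est <- paths(seq_len(n))
  total <- stats::cov(zx, zy) / stats::var(zx)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    p <- paths(i)
    p[["a"]] * p[["b"]]
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 6))
  structure(list(a = unname(est[["a"]]), b = unname(est[["b"]]),
                 direct = unname(est[["c_prime"]]),
                 indirect = unname(est[["a"]] * est[["b"]]),
                 total = total, ci_low = ci[1L], ci_high = ci[2L],
                 conf = conf, boot = boot, n = n, n_boot = as.integer(n_boot),
                 seed = seed),
            class = "mediation")
}

#' @export
print.mediation <- function(x, ...) {
  cat("Mediation (standardized paths, ", x$n_boot,
      " percentile-bootstrap samples):\n", sep = "")
  cat(sprintf("  a = %.4f, b = %.4f, direct = %.4f\n", x$a, x$b, x$direct))
  cat(sprintf("  indirect = %.4f, %g%% CI [%.4f, %.4f], total = %.4f\n",
              x$indirect, 100 * x$conf, x$ci_low, x$ci_high, x$total))
  invisible(x)
}

#' Paired-samples t test with Cohen's d
#'
#' Standard paired t test on the differences, with the paired effect size
#' \eqn{d = \bar{d} / s_d = t / \sqrt{n}}.
#'
#' @param a,b paired numeric vectors.
#' @return A \code{"group_comparison"} with the t statistic, df = n - 1,
#'   two-sided p and Cohen's d.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must be paired", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE)
  new_group_comparison("Paired t test", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value,
                       mean(d) / stats::sd(d), "Cohen's d", n)
}

#' One-sample t test
#'
#' @param a numeric vector.
#' @param mu null value to test against.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return A \code{"group_comparison"} with Cohen's d =
#'   \code{(mean(a) - mu) / sd(a)}.
#' @export
one_sample_t <- function(a, mu = 0, alternative = "two.sided") {
  n <- length(a)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(a, mu = mu, alternative = alternative)
  new_group_comparison("One-sample t test", unname(tt$statistic),
                       unname(tt$parameter), tt$p.value,
                       (mean(a) - mu) / stats::sd(a), "Cohen's d", n)
}

#' Cohen's d from a paired t statistic
#'
#' The paired-design identity \eqn{d = t / \sqrt{n}}.
#'
#' @param t t statistic from a paired (or one-sample) test.
#' @param n number of pairs (observations).
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(2.514, 68)
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Epsilon-squared effect size for Kruskal-Wallis
#'
#' The rank-based effect size \eqn{\epsilon^2 = H / (n - 1)}, equivalently
#' \eqn{H (n + 1) / (n^2 - 1)}, for a Kruskal-Wallis H computed over n
#' observations.
#'
#' @param H Kruskal-Wallis statistic (tie-corrected).
#' @param n total number of observations.
#' @return Epsilon-squared, in [0, 1].
#' @examples
#' epsilon_squared(239, 400)
#' @export
epsilon_squared <- function(H, n) H / (n - 1)

#' Kruskal-Wallis test with epsilon-squared
#'
#' Tie-corrected Kruskal-Wallis H with chi-squared p on g - 1 df and the
#' epsilon-squared effect size. When every pooled observation is identical
#' the tie correction degenerates; H is 0 by convention.
#'
#' @param groups list of numeric vectors, one per group.
#' @return A \code{"group_comparison"} with the H statistic, df, p,
#'   epsilon-squared and group sizes.
#' @export
kruskal_wallis_eps2 <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  n <- sum(sizes)
  if (n < length(groups) + 1L)
    stop("too few observations", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), sizes)
  if (length(unique(pooled)) == 1L) {
    return(new_group_comparison("Kruskal-Wallis", 0, length(groups) - 1L, 1,
                                0, "epsilon squared", n,
                                list(group_sizes = sizes)))
  }
  kt <- stats::kruskal.test(pooled, factor(g))
  H <- unname(kt$statistic)
  new_group_comparison("Kruskal-Wallis", H, unname(kt$parameter), kt$p.value,
                       epsilon_squared(H, n), "epsilon squared", n,
                       list(group_sizes = sizes))
}

#' Dwass-Steel-Critchlow-Fligner pairwise post hoc test
#'
#' All-pairs nonparametric comparisons following a Kruskal-Wallis test. For
#' each pair of groups the pooled ranks (average ranks for ties) give a
#' Wilcoxon rank-sum statistic; the standardized statistic, scaled by
#' \eqn{\sqrt{2}}, is referred to the studentized range distribution with g
#' groups and infinite degrees of freedom — the large-sample approximation
#' used by common implementations. The variance carries the usual tie
#' correction.
#'
#' @param groups list of at least 3 numeric vectors, each of size >= 2.
#' @return A data.frame with columns \code{group1}, \code{group2},
#'   \code{statistic} (signed: positive when group2 ranks higher) and
#'   \code{p}.
#' @export
dscf_posthoc <- function(groups) {
  stopifnot(is.list(groups))
  g <- length(groups)
  if (g < 3L) stop("need at least 3 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs >= 2 observations", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(g))
  pairs <- utils::combn(g, 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    xi <- groups[[i]]; xj <- groups[[j]]
    ni <- length(xi); nj <- length(xj)
    N <- ni + nj
    pooled <- c(xi, xj)
    r <- rank(pooled)
    Rj <- sum(r[(ni + 1L):N])
    ties <- table(pooled)
    sigma2 <- (ni * nj / 24) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0)
      return(c(statistic = 0, p = 1))
    stat <- (Rj - nj * (N + 1) / 2) / sqrt(sigma2)
    p <- stats::ptukey(abs(stat), nmeans = g, df = Inf, lower.tail = FALSE)
    c(statistic = stat, p = p)
  })
  data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
             statistic = res["statistic", ], p = res["p", ],
             stringsAsFactors = FALSE, row.names = NULL)
}
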