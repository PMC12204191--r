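#' Wilcoxon rank-sum test with z statistic
#'
#' Midrank-based rank-sum test. For small tie-free samples the p-value comes
#' from exhaustive enumeration of the rank-sum distribution; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. The z statistic (reported in either case from the
#' normal approximation) is positive when `a` tends to exceed `b`.
#'
#' @param a,b Numeric vectors (each nonempty).
#' @param alternative `"two.sided"`, `"greater"` (a > b), or `"less"`.
#' @param exact_max Use exact enumeration when `choose(na+nb, na)` is at
#'   most this and there are no ties.
#' @return List of class `rank_sum_test`: `statistic` (z), `p`, `n` (per
#'   group), `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2/20
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 1e5) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stopf("rank_sum_test: empty group")
  N <- na + nb
  all_v <- c(a, b)
  r <- rank(all_v)                       # midranks
  W <- sum(r[seq_len(na)])
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  mu <- na * (N + 1) / 2
  tie_term <- sum(ties^3 - ties) / ((N) * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  cc <- if (sigma > 0) sign(W - mu) * 0.5 else 0
  z <- if (sigma > 0) (W - mu - cc) / sigma else 0

  method <- "rank-sum (normal approximation)"
  if (!has_ties && choose(N, na) <= exact_max) {
    method <- "rank-sum (exact enumeration)"
    combos <- utils::combn(N, na)
    ws <- colSums(matrix(seq_len(N)[combos], nrow = na))
    p_ge <- mean(ws >= W)
    p_le <- mean(ws <= W)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
  } else {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(list(statistic = z, p = p, n = c(na, nb), method = method),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("%s: z = %.3f, p = %.4g, n = (%d, %d)\n",
              x$method, x$statistic, x$p, x$n[1], x$n[2]))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values, with rejection flags at level
#' `q`.
#'
#' @param pvals P-values in (0, 1].
#' @param q FDR level for the rejection flags.
#' @return List with `adjusted` (BH-adjusted p-values, same order as input)
#'   and `reject` (logical).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stopf("fdr_correct: p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

# Per-timepoint rank-sum z for a fixed rank matrix. `R` is (na+nb) x T of
# per-column midranks; `idx` selects the rows of group A. Vectorised so the
# permutation loop costs one colSums per permutation.
ranksum_z_cols <- function(R, idx, na, nb, sigma, mu) {
  W <- colSums(R[idx, , drop = FALSE])
  d <- W - mu
  (d - sign(d) * 0.5) / sigma
}

#' Cluster-based permutation test for time series
#'
#' Compares two sets of traces (one row per exchangeable unit, typically a
#' subject-level condition mean) on a common time grid. Per timepoint a
#' rank-sum z is computed; maximal runs of timepoints with pointwise
#' two-sided p below `cluster_alpha` form clusters whose mass (sum of |z|,
#' or extent) is compared against the permutation distribution of the
#' maximum cluster mass under random relabelling of units. Cluster p-values
#' are `(1 + #{perm max >= observed}) / (n_perm + 1)` and can never fall
#' below `1/(n_perm + 1)`.
#'
#' @param traces_a,traces_b Numeric matrices, units x timepoints, on the
#'   same grid.
#' @param n_perm Number of permutations.
#' @param cluster_alpha Cluster-forming pointwise alpha.
#' @param seed Seed for the permutation draw (mandatory for reproducible
#'   pipelines).
#' @param grid Optional time grid for reporting cluster start/end times.
#' @param statistic `"mass"` (sum of |z|) or `"extent"` (number of
#'   timepoints).
#' @return Object of class `cluster_test`: data frame `clusters`
#'   (`start`, `end`, `mass`, `p`), plus `z` (pointwise), `n_perm`,
#'   `cluster_alpha`.
#' @export
cluster_permutation_test <- function(traces_a, traces_b, n_perm = 1000,
                                     cluster_alpha = 0.05, seed = 1L,
                                     grid = NULL,
                                     statistic = c("mass", "extent")) {
  statistic <- match.arg(statistic)
  if (ncol(traces_a) != ncol(traces_b)) {
    stopf("cluster_permutation_test: mismatched time grids (%d vs %d)",
          ncol(traces_a), ncol(traces_b))
  }
  na <- nrow(traces_a); nb <- nrow(traces_b)
  if (na < 2L || nb < 2L) {
    stopf("cluster_permutation_test: need at least 2 units per group")
  }
  M <- rbind(traces_a, traces_b)
  Tn <- ncol(M)
  if (is.null(grid)) grid <- seq_len(Tn)
  N <- na + nb
  R <- apply(M, 2, rank)
  mu <- na * (N + 1) / 2
  # tie-corrected per-column variance
  tie_term <- apply(M, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt) / (N * (N - 1))
  })
  sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
  sigma[sigma == 0] <- Inf

  cluster_masses <- function(z) {
    p <- 2 * stats::pnorm(-abs(z))
    sig <- p < cluster_alpha
    if (!any(sig)) return(NULL)
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    kk <- which(r$values)
    data.frame(i0 = starts[kk], i1 = ends[kk],
               mass = vapply(kk, function(j) {
                 if (statistic == "mass")
                   sum(abs(z[starts[j]:ends[j]]))
                 else ends[j] - starts[j] + 1
               }, 0))
  }

  z_obs <- ranksum_z_cols(R, seq_len(na), na, nb, sigma, mu)
  obs <- cluster_masses(z_obs)

  max_mass <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(N, na)
      zp <- ranksum_z_cols(R, idx, na, nb, sigma, mu)
      cl <- cluster_masses(zp)
      if (is.null(cl)) 0 else max(cl$mass)
    }, 0)
  })

  clusters <- if (is.null(obs)) {
    data.frame(start = numeric(0), end = numeric(0), mass = numeric(0),
               p = numeric(0))
  } else {
    data.frame(start = grid[obs$i0], end = grid[obs$i1], mass = obs$mass,
               p = vapply(obs$mass,
                          function(m) (1 + sum(max_mass >= m)) / (n_perm + 1),
                          0))
  }
  structure(list(clusters = clusters, z = z_obs, grid = grid,
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 statistic = statistic, seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %d permutations, alpha %.2f)\n",
              x$statistic, x$n_perm, x$cluster_alpha))
  if (nrow(x$clusters) == 0L) {
    cat("  no clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Midrank-based rho with the t approximation for the p-value.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("spearman_cor: need at least 3 complete pairs")
  rho <- stats::cor(rank(x), rank(y))
  if (!is.finite(rho)) stopf("spearman_cor: correlation undefined (constant input)")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Serialize a test result to a JSON record
#'
#' @param result A `rank_sum_test` or `cluster_test`.
#' @param params Optional extra parameter list stored alongside.
#' @return JSON string `{method, statistic, p, n, params, seed}`.
#' @export
test_result_json <- function(result, params = NULL) {
  rec <- if (inherits(result, "rank_sum_test")) {
    list(method = result$method, statistic = result$statistic, p = result$p,
         n = result$n, params = params)
  } else if (inherits(result, "cluster_test")) {
    list(method = sprintf("cluster permutation (%s)", result$statistic),
         clusters = result$clusters, n_perm = result$n_perm,
         cluster_alpha = result$cluster_alpha, params = params,
         seed = result$seed)
  } else {
    stopf("test_result_json: unsupported result class")
  }
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"))
}
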