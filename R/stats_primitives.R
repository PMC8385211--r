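# Statistical kernels shared by the null models and the network stage:
# Spearman correlation with a t-approximation p-value, Wilcoxon rank-sum,
# a permutation Mantel test, Bray-Curtis dissimilarity and alpha diversity.

test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n = n),
            class = "ma_test_result")
}

#' @export
print.ma_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation with significance
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The default two-sided p-value uses the t approximation with n - 2
#' degrees of freedom, appropriate at survey sample sizes; `exact = TRUE`
#' enumerates all permutations of `y` (feasible for n <= 8) and returns
#' the exact two-sided permutation p.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param exact logical; exact permutation p instead of the t
#'   approximation.
#' @return a test-result list: `statistic` (rho), `p_value`, `method`, `n`.
#'   Constant input yields `statistic = NaN` with `p_value = NA` and a
#'   flagging method note.
#' @export
spearman_rho_p <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(NaN, NA_real_, "spearman (undefined: constant input)", n))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(seq_len(n))
    rhos <- vapply(perms, function(p) stats::cor(rx, ry[p]), numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(test_result(rho, p, "spearman (exact permutation)", n))
  }
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  test_result(rho, p, "spearman (t approximation)", n)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration when the pooled size is at most 12 with no ties,
#' otherwise the normal approximation with tie and continuity correction
#' (via [stats::wilcox.test()]). Two-sided p is twice the smaller
#' one-sided p, capped at 1.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return a test-result list with the rank-sum `statistic` (Mann-Whitney
#'   W for `x`), `p_value`, `method`, `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- n <= 12 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  test_result(unname(res$statistic), min(res$p.value, 1),
              if (use_exact) "wilcoxon rank-sum (exact)"
              else "wilcoxon rank-sum (normal approximation)", n)
}

#' Mantel permutation test
#'
#' r is the Pearson (optionally Spearman) correlation of the upper
#' triangles of two distance matrices; p is the one-tailed permutation
#' probability (1 + #\{r_perm >= r_obs\}) / (permutations + 1), permuting
#' rows and columns of `Db` jointly.
#'
#' @param Da,Db symmetric distance matrices with identical labels in
#'   identical order.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param method `"pearson"` (the classical test) or `"spearman"`.
#' @return a test-result list (`statistic` = Mantel r).
#' @export
mantel_test <- function(Da, Db, permutations = 999, seed = 1,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Da <- as.matrix(Da)
  Db <- as.matrix(Db)
  if (!all(dim(Da) == dim(Db))) stop("distance matrices differ in size")
  if (!is.null(rownames(Da)) && !is.null(rownames(Db)) &&
      !identical(rownames(Da), rownames(Db))) {
    stop("distance matrices must share labels in the same order")
  }
  n <- nrow(Da)
  ut <- upper.tri(Da)
  a <- Da[ut]
  r_obs <- stats::cor(a, Db[ut], method = method)
  r_perm <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      p <- sample.int(n)
      stats::cor(a, Db[p, p][ut], method = method)
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (permutations + 1)
  test_result(r_obs, p, sprintf("mantel (%s, %d permutations)",
                                method, permutations), n)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC = sum(|x - y|) / sum(x + y), in \[0, 1\]; 0 iff the vectors are
#' equal, 1 for disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return a single dissimilarity; `NaN` (flagged by warning) when both
#'   vectors are all zero.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    warning("both vectors all-zero: Bray-Curtis undefined")
    return(NaN)
  }
  sum(abs(x - y)) / tot
}

#' Alpha diversity of one sample
#'
#' Richness (observed OTUs), Chao1 in the classic form
#' S + F1^2 / (2 F2) (bias-corrected S + F1 (F1 - 1) / (2 (F2 + 1)) when
#' F2 = 0), and ACE, the abundance-based coverage estimator with the
#' conventional rare/abundant cutoff of 10 reads:
#' ACE = S_abund + S_rare / C + F1 gamma^2 / C, with sample coverage
#' C = 1 - F1 / N_rare and gamma^2 the coefficient of variation of the
#' rare-class frequencies (floored at 0).
#'
#' @param counts non-negative integer vector with at least one positive
#'   entry.
#' @param rare_cutoff reads at or below which an OTU counts as rare for
#'   ACE (default 10).
#' @return list with `richness`, `chao1`, `ace` (`ace` is `NaN` when the
#'   coverage estimate is 0, i.e. all rare OTUs are singletons).
#' @export
#' @examples
#' alpha_diversity(c(1, 1, 2, 5)) # richness 4, chao1 6
alpha_diversity <- function(counts, rare_cutoff = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts zero: diversity undefined")
  if (any(counts != round(counts))) stop("counts must be integers")
  S <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / (2 * (F2 + 1))
  rare <- counts[counts <= rare_cutoff]
  S_abund <- sum(counts > rare_cutoff)
  S_rare <- length(rare)
  N_rare <- sum(rare)
  if (S_rare == 0) {
    ace <- S
  } else {
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      ace <- NaN
    } else {
      i <- seq_len(rare_cutoff)
      Fi <- vapply(i, function(k) sum(rare == k), numeric(1))
      gamma2 <- max(
        S_rare / C_ace * sum(i * (i - 1) * Fi) / (N_rare * (N_rare - 1)) - 1,
        0
      )
      ace <- S_abund + S_rare / C_ace + F1 / C_ace * gamma2
    }
  }
  list(richness = S, chao1 = chao1, ace = ace)
}

#' Per-sample alpha diversity table
#'
#' @param table a [community_table()].
#' @param rare_cutoff ACE rare cutoff, see [alpha_diversity()].
#' @return data.frame with one row per sample: `sample_id`, `group`,
#'   `richness`, `chao1`, `ace`.
#' @export
alpha_diversity_table <- function(table, rare_cutoff = 10) {
  rows <- lapply(table$sample_ids, function(s) {
    a <- alpha_diversity(table$counts[, s], rare_cutoff)
    data.frame(sample_id = s, group = unname(table$sample_groups[s]),
               richness = a$richness, chao1 = a$chao1, ace = a$ace)
  })
  do.call(rbind, rows)
}
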