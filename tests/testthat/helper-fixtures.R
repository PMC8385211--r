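# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written without the package's own code paths (Floyd-Warshall
# + path counting for graph metrics, explicit permutation enumeration for
# exact null distributions).

# -- fixtures ---------------------------------------------------------------

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

toy_table <- function(counts = NULL, groups = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 5, 5, 0, 3, 7), nrow = 3,
                     dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep(c("monsoon", "intermonsoon"),
                                  length.out = ncol(counts)),
                              colnames(counts))
  }
  community_table(counts, groups)
}

random_community <- function(n_otus, n_samples, depth = 200, seed = 1) {
  withr::with_seed(seed, {
    p <- rlnorm(n_otus, 0, 1)
    counts <- sapply(seq_len(n_samples), function(i) {
      rmultinom(1, depth, p * rlnorm(n_otus, 0, 0.5))[, 1]
    })
    dimnames(counts) <- list(sprintf("OTU%03d", seq_len(n_otus)),
                             sprintf("s%02d", seq_len(n_samples)))
    community_table(counts, stats::setNames(
      rep(c("monsoon", "intermonsoon"), length.out = n_samples),
      colnames(counts)))
  })
}

# Metacommunity fixture where samples 1 and 2 are an identical pair drawn
# from a shared skewed pool.
identical_pair_table <- function(seed = 42) {
  withr::with_seed(seed, {
    nsp <- 100
    pool <- rlnorm(nsp, 0, 1)
    pool <- pool / sum(pool)
    draws <- sapply(1:10, function(i) rmultinom(1, 500, pool)[, 1])
    ident <- rmultinom(1, 500, pool)[, 1]
    counts <- cbind(ident, ident, draws)
    dimnames(counts) <- list(paste0("OTU", seq_len(nsp)),
                             paste0("s", 1:12))
    community_table(counts, stats::setNames(
      rep(c("a", "b"), 6), colnames(counts)))
  })
}

# Metacommunity fixture where samples 1 and 2 have disjoint OTU sets of
# richness 40 drawn from a 400-species pool of equally common species.
disjoint_pair_table <- function() {
  nsp <- 400
  c1 <- integer(nsp)
  c2 <- integer(nsp)
  c1[1:40] <- 10
  c2[41:80] <- 10
  counts <- cbind(c1, c2, matrix(1L, nsp, 4))
  dimnames(counts) <- list(paste0("OTU", seq_len(nsp)), paste0("s", 1:6))
  community_table(counts, stats::setNames(rep(c("a", "b"), 3),
                                          colnames(counts)))
}

# -- permutation utilities --------------------------------------------------

# Heap's algorithm: independent of the package's recursive enumerator.
heap_permutations <- function(n) {
  out <- list()
  a <- seq_len(n)
  gen <- function(k) {
    if (k == 1) {
      out[[length(out) + 1]] <<- a
    } else {
      for (i in seq_len(k)) {
        gen(k - 1)
        if (k %% 2 == 0) {
          tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
        } else {
          tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp
        }
      }
    }
  }
  gen(n)
  out
}

# Exact betaNTI by enumerating every tip permutation; betaMNTD through
# picante::comdistnt (an implementation independent of the package's).
exact_bnti_enumeration <- function(counts, D, weighted = TRUE) {
  comm <- t(counts) # picante convention: samples x taxa
  obs <- as.matrix(picante::comdistnt(comm, D, abundance.weighted = weighted))
  perms <- heap_permutations(nrow(D))
  nulls <- vapply(perms, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    as.matrix(picante::comdistnt(comm, Dp,
                                 abundance.weighted = weighted))[1, 2]
  }, numeric(1))
  (obs[1, 2] - mean(nulls)) / sqrt(mean(nulls^2) - mean(nulls)^2)
}

# -- brute-force graph oracle ----------------------------------------------

# All node- and network-level metrics from first principles on a 0/1
# adjacency matrix (n <= ~10): Floyd-Warshall distances, shortest-path
# counting for betweenness, power iteration (with +I shift, safe for
# bipartite graphs) for eigenvector centrality.
oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  # shortest-path counts
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    lvls <- sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))
    for (l in lvls) {
      for (v in which(d[s, ] == l)) {
        prev <- which(A[, v] == 1 & d[s, ] == l - 1)
        sig[v] <- sum(sig[prev])
      }
    }
    sigma[s, ] <- sig
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(d[i, ])] <- cid
    }
  }
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(d[s, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    k <- sum(comp == comp[v])
    if (k >= 3) tot / ((k - 1) * (k - 2) / 2) else 0
  }, numeric(1))
  clo <- vapply(seq_len(n), function(v) {
    k <- sum(comp == comp[v])
    if (k < 2) 0 else (k - 1) / sum(d[v, comp == comp[v]])
  }, numeric(1))
  sizes <- tabulate(comp)
  largest <- which.max(sizes)
  eig <- numeric(n)
  vs <- which(comp == largest)
  if (length(vs) >= 2) {
    B <- A[vs, vs, drop = FALSE] + diag(length(vs))
    x <- rep(1, length(vs))
    for (it in 1:5000) {
      x <- as.numeric(B %*% x)
      x <- x / sqrt(sum(x^2))
    }
    eig[vs] <- abs(x)
  }
  loc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) 0 else sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  dl <- d[vs, vs, drop = FALSE]
  off <- dl[row(dl) != col(dl)]
  list(degree = rowSums(A), betweenness = btw, closeness = clo,
       eigenvector = eig, clustering = mean(loc),
       diameter = if (length(off)) max(off) else NA_real_,
       apl = if (length(off)) mean(off) else NA_real_)
}

# Random simple graph as 0/1 adjacency with a unique largest component.
random_adjacency <- function(n, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(0L, n, n)
      A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
      A <- A + t(A)
      reach <- (diag(n) + A) %*% (diag(n) + A) %*% (diag(n) + A) %*%
        (diag(n) + A) %*% (diag(n) + A) %*% (diag(n) + A) %*%
        (diag(n) + A) > 0
      comp <- rep(NA_integer_, n)
      cid <- 0
      for (i in seq_len(n)) {
        if (is.na(comp[i])) {
          cid <- cid + 1
          comp[reach[i, ]] <- cid
        }
      }
      sizes <- tabulate(comp)
      if (sum(sizes == max(sizes)) == 1 && sum(A) > 0) return(A)
    }
  })
}
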