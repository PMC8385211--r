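# Phylogenetic null-model inference of community assembly processes.
#
# For every sample pair the observed beta mean nearest taxon distance
# (betaMNTD) is compared to a null distribution obtained by shuffling tip
# identities on the cophenetic matrix ("taxa shuffle"); the z-score is the
# beta nearest taxon index (betaNTI). Pairs with |betaNTI| < 2 are further
# examined with the Bray-Curtis-based Raup-Crick metric (RC-Bray), whose
# null preserves each sample's richness and total abundance while drawing
# species by metacommunity occupancy and filling individuals by
# metacommunity relative abundance. The joint decision rule assigns one of
# five ecological processes per pair:
#   betaNTI > +2                      -> variable selection
#   betaNTI < -2                      -> homogeneous selection
#   |betaNTI| < 2 and RC > +0.95      -> dispersal limitation
#   |betaNTI| < 2 and RC < -0.95      -> homogenizing dispersal
#   |betaNTI| < 2 and |RC| <= 0.95    -> undominated

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated", "undefined")

#' Beta mean nearest taxon distance between two communities
#'
#' betaMNTD = 0.5 * ( sum_i w_i min_j d(i, j) + sum_j w_j min_i d(i, j) ),
#' where i runs over OTUs present in the first community, j over OTUs
#' present in the second, and the weights w are relative abundances
#' renormalized over present OTUs (`weighted = TRUE`) or uniform over
#' present OTUs (`weighted = FALSE`).
#'
#' @param fa,fb non-negative abundance vectors aligned to the labels of
#'   `D`; each must have at least one positive entry.
#' @param D cophenetic distance matrix over the OTUs.
#' @param weighted abundance-weight the means (default) or treat all
#'   present OTUs equally.
#' @return a single non-negative distance (tree units).
#' @export
beta_mntd <- function(fa, fb, D, weighted = TRUE) {
  stopifnot(length(fa) == nrow(D), length(fb) == nrow(D))
  A <- which(fa > 0)
  B <- which(fb > 0)
  if (length(A) == 0 || length(B) == 0) stop("empty community")
  mA <- apply(D[A, B, drop = FALSE], 1, min)
  mB <- apply(D[A, B, drop = FALSE], 2, min)
  if (weighted) {
    wa <- fa[A] / sum(fa[A])
    wb <- fb[B] / sum(fb[B])
  } else {
    wa <- rep(1 / length(A), length(A))
    wb <- rep(1 / length(B), length(B))
  }
  0.5 * (sum(wa * mA) + sum(wb * mB))
}

#' Shuffle tip identities on a distance matrix
#'
#' One uniformly random permutation applied jointly to rows and columns:
#' the "taxa shuffle" null that randomizes phylogenetic relationships while
#' leaving community composition untouched. The diagonal stays zero and
#' the off-diagonal multiset is preserved.
#'
#' @param D distance matrix.
#' @param seed integer seed.
#' @return the permuted matrix (labels keep their original order).
#' @export
taxa_shuffle <- function(D, seed = 1) {
  p <- with_seed(seed, sample.int(nrow(D)))
  out <- D[p, p]
  dimnames(out) <- dimnames(D)
  out
}

# All-pairs betaMNTD for a weight matrix W (OTUs x samples, columns sum to
# 1 over present OTUs) under distance matrix D, optionally through a tip
# permutation `perm` (rows of D relabelled by perm). Vectorized: M[, s] is
# the distance from every OTU to its nearest member of sample s.
bmntd_all_pairs <- function(W, pres_list, D, perm = NULL) {
  S <- ncol(W)
  n <- nrow(W)
  M <- matrix(0, n, S)
  if (is.null(perm)) {
    for (s in seq_len(S)) {
      M[, s] <- row_mins(D, pres_list[[s]])
    }
  } else {
    for (s in seq_len(S)) {
      M[, s] <- row_mins(D, perm[pres_list[[s]]])[perm]
    }
  }
  X <- crossprod(W, M)
  0.5 * (X + t(X))
}

# Build the weight matrix for betaMNTD from a community table.
bmntd_weights <- function(counts, weighted) {
  W <- counts
  for (s in seq_len(ncol(W))) {
    pres <- W[, s] > 0
    if (!any(pres)) stop("empty community in sample ", colnames(counts)[s])
    if (weighted) {
      W[, s] <- W[, s] / sum(W[, s])
    } else {
      W[pres, s] <- 1 / sum(pres)
    }
  }
  W
}

#' betaNTI for all sample pairs
#'
#' For each pair, betaNTI = (betaMNTD_obs - mean_null) / sd_null over
#' `reps` taxa-shuffle replicates. Each replicate permutes tip identities
#' once and re-evaluates betaMNTD for every pair, so all pairs share the
#' same null draws (the standard formulation). A degenerate null (sd = 0)
#' yields `NA` and is flagged, never +/-Inf.
#'
#' @param table a [community_table()] (typically rarefied).
#' @param tree an [ape::phylo] tree; table OTUs must all be tips.
#' @param reps null replicates (default 999; >= 2 required).
#' @param weighted abundance-weighted betaMNTD (default TRUE).
#' @param seed integer seed.
#' @return object of class `pairwise_assembly`: list of sample-by-sample
#'   matrices `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, plus
#'   `sample_ids`, `sample_groups`, `reps`.
#' @export
beta_nti_matrix <- function(table, tree, reps = 999, weighted = TRUE,
                            seed = 1) {
  if (reps < 2) stop("reps must be >= 2")
  al <- align_tree_table(table, tree)
  D <- cophenetic_matrix(al$tree)
  counts <- al$table$counts[rownames(D), , drop = FALSE]
  W <- bmntd_weights(counts, weighted)
  pres_list <- lapply(seq_len(ncol(W)), function(s) which(counts[, s] > 0))
  obs <- bmntd_all_pairs(W, pres_list, D)
  n <- nrow(D)
  S <- ncol(W)
  sum1 <- matrix(0, S, S)
  sum2 <- matrix(0, S, S)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample.int(n)
      nul <- bmntd_all_pairs(W, pres_list, D, perm)
      sum1 <- sum1 + nul
      sum2 <- sum2 + nul^2
    }
  })
  null_mean <- sum1 / reps
  null_sd <- sqrt(pmax(sum2 / reps - null_mean^2, 0) * reps / (reps - 1))
  bnti <- (obs - null_mean) / null_sd
  bnti[null_sd < 1e-12] <- NA_real_
  diag(bnti) <- NA_real_
  ids <- colnames(counts)
  dimnames(obs) <- dimnames(null_mean) <- dimnames(null_sd) <-
    dimnames(bnti) <- list(ids, ids)
  structure(
    list(bmntd_obs = obs, null_mean = null_mean, null_sd = null_sd,
         bnti = bnti, sample_ids = ids,
         sample_groups = table$sample_groups[ids], reps = reps,
         weighted = weighted),
    class = "pairwise_assembly"
  )
}

#' RC-Bray for all sample pairs
#'
#' For each pair, `reps` null community pairs are simulated: a null
#' community draws species without replacement with probability
#' proportional to metacommunity occupancy frequency until it reaches the
#' observed richness, seats one individual per drawn species, then fills
#' the remaining individuals multinomially with probability proportional
#' to metacommunity relative abundance of the drawn species. RC = 2 *
#' ((#\{null BC < obs BC\} + 0.5 * #\{null BC = obs BC\}) / reps) - 1, in
#' \[-1, 1\]. Sub-seeds are keyed by the unordered pair, so RC(a, b) =
#' RC(b, a) and results do not depend on iteration order.
#'
#' @param table a [community_table()] with >= 2 samples; the metacommunity
#'   is the set of all its samples.
#' @param reps null replicates (default 999).
#' @param seed integer master seed.
#' @return symmetric matrix of RC-Bray values (diagonal `NA`).
#' @export
rc_bray_matrix <- function(table, reps = 999, seed = 1) {
  counts <- table$counts
  S <- ncol(counts)
  if (S < 2) stop("need >= 2 samples")
  nsp <- nrow(counts)
  occ <- rowSums(counts > 0)
  pool_ab <- rowSums(counts)
  pool_ab <- pool_ab / sum(pool_ab)
  rich <- colSums(counts > 0)
  totals <- colSums(counts)
  rc <- matrix(NA_real_, S, S, dimnames = list(colnames(counts),
                                               colnames(counts)))
  xbuf <- numeric(nsp)
  ybuf <- numeric(nsp)
  null_one <- function(richness, total) {
    sp <- sample.int(nsp, richness, replace = FALSE, prob = occ)
    k <- rep(1, richness)
    if (total > richness) {
      k <- k + stats::rmultinom(1, total - richness, pool_ab[sp])[, 1]
    }
    list(sp = sp, k = k)
  }
  for (a in seq_len(S - 1)) {
    for (b in seq((a + 1), S)) {
      obs_bc <- bray_curtis(counts[, a], counts[, b])
      less <- 0
      equal <- 0
      # draw the two null communities in a canonical (lexicographic)
      # order, so RC(a, b) consumes the seeded stream identically to
      # RC(b, a) whatever the column order of the table
      swap <- colnames(counts)[a] > colnames(counts)[b]
      i1 <- if (swap) b else a
      i2 <- if (swap) a else b
      with_seed(pair_seed(seed, colnames(counts)[a], colnames(counts)[b]), {
        for (r in seq_len(reps)) {
          na <- null_one(rich[i1], totals[i1])
          nb <- null_one(rich[i2], totals[i2])
          xbuf[na$sp] <- na$k
          ybuf[nb$sp] <- nb$k
          idx <- unique(c(na$sp, nb$sp))
          bc <- sum(abs(xbuf[idx] - ybuf[idx])) / (totals[a] + totals[b])
          if (bc < obs_bc - 1e-12) less <- less + 1
          else if (bc <= obs_bc + 1e-12) equal <- equal + 1
          xbuf[na$sp] <- 0
          ybuf[nb$sp] <- 0
        }
      })
      rc[a, b] <- rc[b, a] <- 2 * ((less + 0.5 * equal) / reps) - 1
    }
  }
  rc
}

#' Assign an ecological process to each sample pair
#'
#' Applies the five-way decision rule (see the header of this file) to the
#' betaNTI and RC-Bray matrices and summarizes process fractions for all
#' pairs, within-group pairs, and between-group pairs. Pairs with an
#' undefined betaNTI (degenerate null) are labelled `undefined`, excluded
#' from the five-process fractions and counted separately.
#'
#' @param bnti a `pairwise_assembly` from [beta_nti_matrix()], or a
#'   betaNTI matrix.
#' @param rc an RC-Bray matrix from [rc_bray_matrix()]; may be `NULL`, in
#'   which case all |betaNTI| < 2 pairs count as stochastic but are
#'   labelled `undominated`.
#' @param sample_groups named group vector (taken from `bnti` when it is a
#'   `pairwise_assembly`).
#' @return object of class `process_summary`: `pairs` data.frame (pair,
#'   group relation, betaNTI, RC, process) and `fractions` data.frame
#'   (grouping, process, count, fraction, n_pairs).
#' @export
partition_processes <- function(bnti, rc = NULL, sample_groups = NULL) {
  if (inherits(bnti, "pairwise_assembly")) {
    sample_groups <- sample_groups %||% bnti$sample_groups
    bnti_mat <- bnti$bnti
  } else {
    bnti_mat <- as.matrix(bnti)
  }
  ids <- rownames(bnti_mat)
  S <- nrow(bnti_mat)
  pr <- t(utils::combn(S, 2))
  b <- bnti_mat[pr]
  r <- if (is.null(rc)) rep(NA_real_, nrow(pr)) else as.matrix(rc)[pr]
  process <- ifelse(
    is.na(b), "undefined",
    ifelse(b > 2, "variable_selection",
    ifelse(b < -2, "homogeneous_selection",
    ifelse(!is.na(r) & r > 0.95, "dispersal_limitation",
    ifelse(!is.na(r) & r < -0.95, "homogenizing_dispersal",
           "undominated"))))
  )
  process <- factor(process, levels = PROCESS_LEVELS)
  relation <- if (is.null(sample_groups)) {
    rep("all", nrow(pr))
  } else {
    ga <- sample_groups[ids[pr[, 1]]]
    gb <- sample_groups[ids[pr[, 2]]]
    ifelse(ga == gb, paste0("within_", ga), "between_groups")
  }
  pairs <- data.frame(
    sample_a = ids[pr[, 1]], sample_b = ids[pr[, 2]],
    relation = relation, bnti = b, rc_bray = r, process = process,
    stringsAsFactors = FALSE
  )
  groupings <- unique(c("all", relation))
  fractions <- do.call(rbind, lapply(groupings, function(g) {
    sub <- if (g == "all") pairs else pairs[pairs$relation == g, ]
    defined <- sub$process != "undefined"
    counts <- table(factor(sub$process[defined],
                           levels = setdiff(PROCESS_LEVELS, "undefined")))
    data.frame(
      grouping = g,
      process = names(counts),
      count = as.integer(counts),
      fraction = if (sum(defined) > 0) as.numeric(counts) / sum(defined)
                 else NA_real_,
      n_pairs = sum(defined),
      n_undefined = sum(!defined),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(pairs = pairs, fractions = fractions),
            class = "process_summary")
}

#' @export
print.process_summary <- function(x, ...) {
  cat("process_summary over", nrow(x$pairs), "sample pairs\n")
  print(x$fractions[x$fractions$grouping == "all", c("process", "fraction")],
        row.names = FALSE)
  invisible(x)
}

#' Abundance-weighted environmental niche optimum per OTU
#'
#' optimum_i = sum_s RA_is * E_s / sum_s RA_is: the relative-abundance-
#' weighted mean of the environment over the samples where the OTU occurs.
#'
#' @param table a [community_table()] whose `env` has `env_var`.
#' @param env_var environmental variable name (e.g. `"temperature"`).
#' @return named numeric vector of optima; OTUs absent everywhere are
#'   excluded with a warning.
#' @export
niche_optima <- function(table, env_var) {
  if (is.null(table$env) || !env_var %in% colnames(table$env)) {
    stop("environmental variable '", env_var, "' not present")
  }
  E <- table$env[table$sample_ids, env_var]
  RA <- relative_abundance(table)$values
  tot <- rowSums(RA)
  absent <- tot == 0
  if (any(absent)) {
    warning(sprintf("%d OTUs absent everywhere excluded", sum(absent)))
  }
  opt <- as.numeric(RA %*% E) / tot
  stats::setNames(opt, table$otu_ids)[!absent]
}

#' Mantel correlogram of phylogenetic niche signal
#'
#' Correlates between-OTU niche distance |opt_i - opt_j| with phylogenetic
#' distance class membership. Classes are equal-frequency bins of the
#' observed phylogenetic distances. For class k the statistic is
#' r_k = -cor(niche distance, indicator of class k) over all pairs, so
#' positive r at short distances means closely related OTUs have similar
#' niches. p-values are two-sided permutation probabilities with optima
#' permuted across tips (class membership fixed).
#'
#' @param optima named vector of niche optima (>= 10 OTUs).
#' @param D cophenetic matrix covering the named OTUs.
#' @param n_classes number of distance classes (default 6).
#' @param permutations permutation count (default 199).
#' @param seed integer seed.
#' @return data.frame with one row per class: bounds, mean distance,
#'   `n_pairs`, `mantel_r`, `p_value`. Constant optima give a flagged
#'   degenerate result (all `NA` with a warning).
#' @export
phylo_signal_correlogram <- function(optima, D, n_classes = 6,
                                     permutations = 199, seed = 1) {
  if (length(optima) < 10) stop("need >= 10 OTUs with optima")
  ids <- names(optima)
  D <- as.matrix(D)[ids, ids]
  ut <- upper.tri(D)
  pd <- D[ut]
  breaks <- unique(stats::quantile(pd, probs = seq(0, 1, length.out =
                                                     n_classes + 1)))
  cls <- cut(pd, breaks = breaks, include.lowest = TRUE)
  n_classes <- nlevels(cls)
  if (stats::sd(optima) == 0) {
    warning("constant optima: correlogram degenerate")
    return(data.frame(
      class = seq_len(n_classes), lower = utils::head(breaks, -1),
      upper = breaks[-1], n_pairs = as.integer(table(cls)),
      mantel_r = NA_real_, p_value = NA_real_
    ))
  }
  ind <- lapply(levels(cls), function(l) cls == l)
  class_r <- function(opt) {
    nd <- abs(outer(opt, opt, "-"))[ut]
    vapply(ind, function(m) -stats::cor(nd, as.numeric(m)), numeric(1))
  }
  r_obs <- class_r(optima)
  exceed <- integer(n_classes)
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      r_perm <- class_r(sample(optima))
      exceed <- exceed + (abs(r_perm) >= abs(r_obs) - 1e-12)
    }
  })
  p <- (1 + exceed) / (permutations + 1)
  data.frame(
    class = seq_len(n_classes), lower = utils::head(breaks, -1),
    upper = breaks[-1], n_pairs = as.integer(table(cls)),
    mantel_r = r_obs, p_value = p
  )
}
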