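# Thresholded Spearman co-occurrence network and its diagnostics: node and
# network topology, scale-free fit, Erdos-Renyi small-world baseline,
# natural-connectivity robustness under node removal, Louvain modularity,
# and the label-pair edge census.

#' Drop low-count OTUs before network construction
#'
#' Keeps OTUs with strictly more than `min_total - 1` reads summed over all
#' samples (default: more than 20 sequences, i.e. total >= 21).
#'
#' @param table a [community_table()].
#' @param min_total minimum total count to keep an OTU (default 21).
#' @return the filtered [community_table()]; an empty result is an error.
#' @export
filter_min_sequences <- function(table, min_total = 21) {
  keep <- rowSums(table$counts) >= min_total
  if (!any(keep)) stop("no OTUs with total count >= ", min_total)
  community_table(table$counts[keep, , drop = FALSE],
                  table$sample_groups, table$env)
}

#' Label OTUs by group enrichment
#'
#' Wilcoxon rank-sum test on per-sample relative abundances between the
#' two groups; OTUs with p < `alpha` are labelled with the group holding
#' the larger rank sum, the rest are `"Others"`.
#'
#' @param table a [community_table()] whose metadata has exactly two
#'   groups.
#' @param alpha significance level (default 0.05).
#' @return named character vector OTU -> label (a group name or
#'   `"Others"`).
#' @export
enrichment_labels <- function(table, alpha = 0.05) {
  groups <- unique(table$sample_groups)
  if (length(groups) != 2) stop("need exactly two groups")
  ga <- table$sample_ids[table$sample_groups == groups[1]]
  gb <- table$sample_ids[table$sample_groups == groups[2]]
  if (length(ga) < 3 || length(gb) < 3) {
    warning("a group has < 3 samples: enrichment test underpowered")
  }
  RA <- relative_abundance(table)$values
  labels <- vapply(seq_len(nrow(RA)), function(i) {
    x <- RA[i, ga]
    y <- RA[i, gb]
    res <- wilcoxon_rank_sum(x, y)
    if (is.na(res$p_value) || res$p_value >= alpha) return("Others")
    rk <- rank(c(x, y))
    mean_rank_a <- mean(rk[seq_along(x)])
    mean_rank_b <- mean(rk[-seq_along(x)])
    if (mean_rank_a > mean_rank_b) groups[1] else groups[2]
  }, character(1))
  stats::setNames(labels, table$otu_ids)
}

#' Build the thresholded Spearman co-occurrence network
#'
#' Every OTU pair is tested with the mid-rank Spearman correlation and its
#' t-approximation p-value; an edge is kept iff |rho| > `r_threshold` and
#' p < `p_threshold` (optionally Benjamini-Hochberg adjusted). Isolated
#' nodes are dropped from the graph but counted in the report.
#'
#' @param relabund a [relative_abundance()] object over pre-filtered OTUs
#'   with >= 4 samples.
#' @param r_threshold correlation magnitude threshold (default 0.8).
#' @param p_threshold significance threshold (default 0.01).
#' @param adjust_p apply Benjamini-Hochberg correction to the pair
#'   p-values before thresholding (default FALSE, mirroring plain
#'   "p < 0.01" construction).
#' @param node_labels optional named OTU -> label vector (e.g. from
#'   [enrichment_labels()]) stored as a node attribute.
#' @param node_classes optional named OTU -> abundance category vector.
#' @return object of class `co_network`: `graph` (an [igraph] graph whose
#'   edges carry `rho`, `p`, `sign`), `edges` data.frame, `nodes`
#'   data.frame (label, class, mean relative abundance), `n_tested`,
#'   `n_isolated`, thresholds.
#' @export
build_network <- function(relabund, r_threshold = 0.8, p_threshold = 0.01,
                          adjust_p = FALSE, node_labels = NULL,
                          node_classes = NULL) {
  stopifnot(inherits(relabund, "rel_abundance"))
  V <- relabund$values
  n <- ncol(V) # samples
  if (n < 4) stop("need >= 4 samples")
  if (r_threshold < 0 || r_threshold > 1) stop("r_threshold outside [0, 1]")
  ranks <- t(apply(V, 1, rank))
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[is.na(rho)] <- 0 # constant OTUs correlate with nothing
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  if (adjust_p) pv <- stats::p.adjust(pv, method = "BH")
  keep <- abs(rho[ut]) > r_threshold & pv < p_threshold
  edges <- data.frame(
    otu_a = rownames(V)[ut[keep, 1]],
    otu_b = rownames(V)[ut[keep, 2]],
    rho = rho[ut][keep],
    p = pv[keep],
    sign = ifelse(rho[ut][keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  connected <- unique(c(edges$otu_a, edges$otu_b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = connected)
  mean_ra <- rowMeans(V)
  nodes <- data.frame(
    otu_id = connected,
    label = if (is.null(node_labels)) NA_character_
            else unname(node_labels[connected]),
    class = if (is.null(node_classes)) NA_character_
            else unname(node_classes[connected]),
    mean_ra = unname(mean_ra[connected]),
    stringsAsFactors = FALSE
  )
  structure(
    list(graph = g, edges = edges, nodes = nodes,
         n_tested = nrow(V), n_isolated = nrow(V) - length(connected),
         r_threshold = r_threshold, p_threshold = p_threshold),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "co_network: %d nodes, %d edges (%d OTUs tested, %d isolated)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$n_tested, x$n_isolated
  ))
  invisible(x)
}

as_graph <- function(net) {
  if (inherits(net, "co_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a co_network or igraph graph")
}

#' Node-level topological metrics
#'
#' Degree (neighbor count), betweenness (fraction of shortest paths
#' through the node, normalized by (n-1)(n-2)/2 within each connected
#' component), closeness ((reachable - 1) / sum of distances within the
#' component), and eigenvector centrality (principal eigenvector of the
#' adjacency matrix of the largest component, unit L2 norm; nodes outside
#' it get 0).
#'
#' @param net a `co_network` or [igraph] graph.
#' @return data.frame: `node`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
node_metrics <- function(net) {
  g <- as_graph(net)
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  }
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  btw <- clo <- eig <- stats::setNames(numeric(igraph::vcount(g)), nm)
  comps <- igraph::components(g)
  largest <- which.max(comps$csize)
  for (cid in seq_len(comps$no)) {
    vs <- which(comps$membership == cid)
    sub <- igraph::induced_subgraph(g, vs)
    snm <- igraph::V(sub)$name
    k <- length(vs)
    if (k >= 3) {
      btw[snm] <- igraph::betweenness(sub) / ((k - 1) * (k - 2) / 2)
    }
    if (k >= 2) {
      clo[snm] <- igraph::closeness(sub, normalized = TRUE)
    }
    if (cid == largest && k >= 2) {
      A <- as.matrix(igraph::as_adjacency_matrix(sub))
      ev <- eigen(A, symmetric = TRUE)
      v <- abs(ev$vectors[, 1])
      eig[snm] <- v / sqrt(sum(v^2))
    }
  }
  data.frame(node = nm, degree = as.numeric(deg[nm]),
             betweenness = as.numeric(btw[nm]),
             closeness = as.numeric(clo[nm]),
             eigenvector = as.numeric(eig[nm]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network-level topological metrics
#'
#' Average degree 2E/N, connectance E / (N(N-1)/2), diameter and average
#' path length in hop units on the largest component, and the global
#' clustering coefficient as the mean local clustering (nodes with degree
#' < 2 contribute 0).
#'
#' @param net a `co_network` or [igraph] graph with >= 2 nodes.
#' @return list: `n_nodes`, `n_edges`, `average_degree`, `connectance`,
#'   `diameter`, `average_path_length`, `clustering`; diameter/APL are
#'   `NA` when there are no edges.
#' @export
network_metrics <- function(net) {
  g <- as_graph(net)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N < 2) stop("need >= 2 nodes")
  if (E == 0) {
    diam <- apl <- NA_real_
    clus <- 0
  } else {
    comps <- igraph::components(g)
    sub <- igraph::induced_subgraph(g, which(comps$membership ==
                                               which.max(comps$csize)))
    diam <- igraph::diameter(sub, weights = NA)
    apl <- igraph::mean_distance(sub, weights = NA)
    loc <- igraph::transitivity(g, type = "local", isolates = "zero")
    clus <- mean(loc)
  }
  list(n_nodes = N, n_edges = E, average_degree = 2 * E / N,
       connectance = E / (N * (N - 1) / 2), diameter = diam,
       average_path_length = apl, clustering = clus)
}

#' R-squared of a power-law fit to the degree distribution
#'
#' Least-squares fit of log10(frequency) against log10(degree) over
#' degrees with nonzero frequency. Returns the fit R-squared together with
#' the slope, so a flat (slope ~ 0) perfect fit is distinguishable from a
#' scale-free one.
#'
#' @param degrees positive integer degree vector with >= 3 distinct
#'   values (fewer is a flagged `NA` result).
#' @return list: `r_squared`, `slope`, `n_degrees`.
#' @export
powerlaw_fit_r2 <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 3) {
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_degrees = length(k)))
  }
  fit <- stats::lm(log10(f) ~ log10(k))
  ss_tot <- sum((log10(f) - mean(log10(f)))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot < 1e-15) 1 else 1 - ss_res / ss_tot
  list(r_squared = r2, slope = unname(stats::coef(fit)[2]),
       n_degrees = length(k))
}

#' Erdos-Renyi G(n, m) baseline for small-world comparison
#'
#' Uniform random simple graphs with the same node and edge counts as the
#' observed network; returns mean and sd of average path length (largest
#' component) and clustering coefficient over `reps` draws.
#'
#' @param n,m node and edge counts (m <= n(n-1)/2).
#' @param reps number of random graphs (default 100).
#' @param seed integer seed.
#' @return list of means and sds: `apl_mean`, `apl_sd`, `clustering_mean`,
#'   `clustering_sd`.
#' @export
erdos_renyi_baseline <- function(n, m, reps = 100, seed = 1) {
  stopifnot(m <= n * (n - 1) / 2)
  res <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      g <- igraph::sample_gnm(n, m)
      met <- network_metrics(g)
      c(met$average_path_length, met$clustering)
    }, numeric(2))
  })
  list(apl_mean = mean(res[1, ]), apl_sd = stats::sd(res[1, ]),
       clustering_mean = mean(res[2, ]), clustering_sd = stats::sd(res[2, ]))
}

#' Natural connectivity of a graph
#'
#' The logarithm of the average of exponentiated adjacency eigenvalues,
#' lambda_bar = ln((1/N) sum_i exp(lambda_i)): a spectral measure of the
#' redundancy of alternative paths. Computed stably via a log-sum-exp
#' shift; an edgeless graph gives exactly 0.
#'
#' @param net a `co_network`, [igraph] graph, or 0/1 adjacency matrix.
#' @return a single non-negative-definite real value.
#' @export
natural_connectivity <- function(net) {
  A <- if (is.matrix(net)) net
       else as.matrix(igraph::as_adjacency_matrix(as_graph(net)))
  N <- nrow(A)
  if (N == 0) stop("empty graph")
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Robustness curve under node removal
#'
#' Removes a growing fraction of nodes and records the natural
#' connectivity of the remaining graph. `random` removal draws a fresh
#' removal order per replicate (nested, so fractions are comparable along
#' a replicate); `degree_descending` removes hubs first, deterministically
#' (ties broken by node order), with a single replicate.
#'
#' @param net a `co_network` or [igraph] graph.
#' @param strategy `"random"` or `"degree_descending"`.
#' @param max_fraction largest removal fraction (must be < 1).
#' @param steps number of fractions from 0 to `max_fraction` (default 17).
#' @param reps replicates for random removal (default 100).
#' @param seed integer seed.
#' @return data.frame: `fraction`, `n_removed`, `nc_mean`, `nc_sd`,
#'   `strategy`; the fraction-0 row equals the intact network's natural
#'   connectivity.
#' @export
robustness_curve <- function(net, strategy = c("random", "degree_descending"),
                             max_fraction = 0.8, steps = 17, reps = 100,
                             seed = 1) {
  strategy <- match.arg(strategy)
  if (max_fraction >= 1) stop("max_fraction must be < 1")
  g <- as_graph(net)
  N <- igraph::vcount(g)
  fractions <- seq(0, max_fraction, length.out = steps)
  n_remove <- pmin(round(fractions * N), N - 1)
  if (strategy == "degree_descending") reps <- 1
  orders <- if (strategy == "degree_descending") {
    list(order(-igraph::degree(g)))
  } else {
    with_seed(seed, lapply(seq_len(reps), function(i) sample.int(N)))
  }
  nc <- matrix(0, reps, steps)
  for (r in seq_len(reps)) {
    ord <- orders[[r]]
    for (s in seq_len(steps)) {
      keep <- setdiff(seq_len(N), ord[seq_len(n_remove[s])])
      nc[r, s] <- natural_connectivity(igraph::induced_subgraph(g, keep))
    }
  }
  data.frame(
    fraction = fractions, n_removed = n_remove,
    nc_mean = colMeans(nc),
    nc_sd = if (reps > 1) apply(nc, 2, stats::sd) else 0,
    strategy = strategy
  )
}

#' Louvain modularity partition
#'
#' Greedy multi-level maximization of Newman-Girvan modularity
#' Q = sum_c (e_c / E - (d_c / 2E)^2) with seeded tie-breaking.
#'
#' @param net a `co_network` or [igraph] graph with >= 1 edge.
#' @param seed integer seed.
#' @return list: `membership` (named integer vector), `modularity` (Q),
#'   `n_modules`.
#' @export
modularity_partition <- function(net, seed = 1) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) stop("modularity undefined: no edges")
  cl <- with_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  list(
    membership = stats::setNames(as.integer(memb),
                                 igraph::V(g)$name %||%
                                   as.character(seq_along(memb))),
    modularity = igraph::modularity(g, memb),
    n_modules = length(unique(memb))
  )
}

#' Census of positive and negative edges between node label groups
#'
#' For every unordered label pair (including self-pairs), counts positive
#' and negative edges, reproducing the intra-/inter-group association
#' summary of season-enriched network figures.
#'
#' @param net a `co_network` whose edges carry a `sign` column.
#' @param node_labels named OTU -> label map covering every node
#'   (`"Others"` allowed).
#' @return data.frame: `label_a`, `label_b`, `positive`, `negative`.
#' @export
edge_census <- function(net, node_labels) {
  stopifnot(inherits(net, "co_network"))
  e <- net$edges
  la <- node_labels[e$otu_a]
  lb <- node_labels[e$otu_b]
  if (anyNA(la) || anyNA(lb)) stop("all nodes must be labelled")
  key <- ifelse(la <= lb, paste(la, lb, sep = "|"), paste(lb, la, sep = "|"))
  labs <- sort(unique(c(la, lb)))
  combos <- c()
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      combos <- c(combos, paste(labs[i], labs[j], sep = "|"))
    }
  }
  out <- do.call(rbind, lapply(combos, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(label_a = parts[1], label_b = parts[2],
               positive = sum(key == k & e$sign == "positive"),
               negative = sum(key == k & e$sign == "negative"),
               stringsAsFactors = FALSE)
  }))
  out
}
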