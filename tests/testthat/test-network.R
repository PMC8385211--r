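# Co-occurrence network construction and diagnostics.

path_graph <- function() igraph::make_graph(~ A - B, B - C)

test_that("prevalence filter keeps OTUs with more than 20 reads", {
  counts <- matrix(c(21, 20, 100, 0, 0, 0), nrow = 3,
                   dimnames = list(c("keep", "drop", "big"), c("s1", "s2")))
  ct <- toy_table(counts)
  kept <- filter_min_sequences(ct)
  expect_setequal(kept$otu_ids, c("keep", "big"))
  all_big <- toy_table(matrix(100L, 3, 2,
                              dimnames = list(c("a", "b", "c"),
                                              c("s1", "s2"))))
  expect_identical(filter_min_sequences(all_big)$counts, all_big$counts)
  expect_error(filter_min_sequences(ct, min_total = 1000), "no OTUs")
})

test_that("enrichment labels follow direction, significance and symmetry", {
  set.seed(71)
  n <- 12
  # a filler OTU fixes every sample total at 10000, so relative abundances
  # are exactly proportional to counts and the 'up' signal cannot leak
  # into other OTUs compositionally
  counts <- rbind(
    up = c(rpois(n, 50) + 150, rpois(n, 20)),      # higher in group A
    flat = rpois(2 * n, 100),
    noise = rpois(2 * n, 100)
  )
  counts <- rbind(counts, filler = 10000 - colSums(counts))
  colnames(counts) <- paste0("s", seq_len(2 * n))
  groups <- stats::setNames(rep(c("monsoon", "intermonsoon"), each = n),
                            colnames(counts))
  ct <- community_table(counts, groups)
  lab <- enrichment_labels(ct)
  expect_equal(unname(lab["up"]), "monsoon")
  expect_equal(unname(lab["flat"]), "Others")

  swapped <- community_table(counts, stats::setNames(
    rep(c("intermonsoon", "monsoon"), each = n), colnames(counts)))
  lab2 <- enrichment_labels(swapped)
  expect_equal(unname(lab2["up"]), "intermonsoon")

  tiny <- community_table(counts[, c(1, 2, 13, 14)],
                          groups[c(1, 2, 13, 14)])
  expect_warning(enrichment_labels(tiny), "underpowered")
})

test_that("edges require both correlation magnitude and significance", {
  set.seed(73)
  n <- 24
  base <- rnorm(n)
  V <- rbind(
    a = rank(base) + 0,
    b = rank(base) * 2,            # perfect positive rank correlation
    c = max(rank(base)) - rank(base), # perfect negative
    d = rnorm(n),                  # noise
    e = rnorm(n)
  )
  V <- V / rep(colSums(V), each = nrow(V))
  colnames(V) <- paste0("s", 1:n)
  ra <- structure(list(values = V, otu_ids = rownames(V),
                       sample_ids = colnames(V),
                       sample_groups = stats::setNames(rep("g", n),
                                                       colnames(V))),
                  class = "rel_abundance")
  net <- build_network(ra)
  key <- paste(net$edges$otu_a, net$edges$otu_b)
  expect_true("a b" %in% key)
  expect_true("a c" %in% key)
  expect_equal(net$edges$sign[key == "a b"], "positive")
  expect_equal(net$edges$sign[key == "a c"], "negative")
  expect_false(any(c("a d", "d e") %in% key))
  expect_equal(net$n_tested, 5)

  # raising the threshold never adds edges
  net95 <- build_network(ra, r_threshold = 0.95)
  key95 <- paste(net95$edges$otu_a, net95$edges$otu_b)
  expect_true(all(key95 %in% key))
})

test_that("node metrics match hand values on a path and a clique", {
  nm <- node_metrics(path_graph())
  expect_equal(nm$degree, c(1, 2, 1))
  expect_equal(nm$betweenness[nm$node == "B"], 1)
  expect_equal(nm$closeness[nm$node == "A"], 2 / 3)

  k4 <- igraph::make_full_graph(4)
  nk <- node_metrics(k4)
  expect_equal(nk$betweenness, rep(0, 4))
  expect_equal(nk$eigenvector, rep(0.5, 4)) # unit L2 norm, all equal
})

test_that("node and network metrics match the brute-force oracle", {
  for (s in 1:50) {
    A <- random_adjacency(sample(4:8, 1), p = 0.4, seed = s)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    got_n <- node_metrics(g)
    got_g <- network_metrics(g)
    want <- oracle_graph_metrics(A)
    expect_equal(got_n$degree, unname(want$degree), tolerance = 1e-8)
    expect_equal(got_n$betweenness, want$betweenness, tolerance = 1e-8)
    expect_equal(got_n$closeness, want$closeness, tolerance = 1e-8)
    expect_equal(got_n$eigenvector, want$eigenvector, tolerance = 1e-6)
    expect_equal(got_g$clustering, want$clustering, tolerance = 1e-8)
    expect_equal(got_g$diameter, want$diameter)
    expect_equal(got_g$average_path_length, want$apl, tolerance = 1e-8)
  }
})

test_that("network metrics reproduce closed-form fixtures", {
  k3 <- network_metrics(igraph::make_full_graph(3))
  expect_equal(k3$average_degree, 2)
  expect_equal(k3$connectance, 1)
  expect_equal(k3$diameter, 1)
  expect_equal(k3$average_path_length, 1)
  expect_equal(k3$clustering, 1)

  p3 <- network_metrics(path_graph())
  expect_equal(p3$connectance, 2 / 3)
  expect_equal(p3$diameter, 2)
  expect_equal(p3$average_path_length, 4 / 3)
  expect_equal(p3$clustering, 0)

  star <- network_metrics(igraph::make_star(5, mode = "undirected"))
  expect_equal(star$clustering, 0)
  expect_equal(star$diameter, 2)
  expect_gte(star$diameter, star$average_path_length)
})

test_that("power-law fit distinguishes scale-free from flat distributions", {
  k <- 1:10
  freq <- round(1000 * k^-2)
  degrees <- rep(k, freq)
  fit <- powerlaw_fit_r2(degrees)
  expect_equal(fit$r_squared, 1, tolerance = 0.01)
  expect_lt(fit$slope, 0)

  flat <- rep(1:10, each = 5)
  ffit <- powerlaw_fit_r2(flat)
  expect_equal(ffit$r_squared, 1)
  expect_equal(ffit$slope, 0, tolerance = 1e-12)

  expect_true(is.na(powerlaw_fit_r2(c(1, 1, 2, 2))$r_squared))
  set.seed(81)
  r2 <- powerlaw_fit_r2(rpois(200, 5) + 1)$r_squared
  expect_gte(r2, 0)
  expect_lte(r2, 1)
})

test_that("erdos-renyi baseline matches its expectations", {
  base <- erdos_renyi_baseline(100, 500, reps = 200, seed = 5)
  dens <- 500 / choose(100, 2)
  se <- base$clustering_sd / sqrt(200)
  expect_lt(abs(base$clustering_mean - dens), 3 * se)
  expect_identical(erdos_renyi_baseline(100, 500, reps = 20, seed = 9),
                   erdos_renyi_baseline(100, 500, reps = 20, seed = 9))
})

test_that("natural connectivity matches spectra and shrinks with edges", {
  expect_equal(natural_connectivity(igraph::make_empty_graph(5,
                                                            directed = FALSE)),
               0)
  expect_equal(natural_connectivity(igraph::make_full_graph(3)),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-10)
  expect_equal(natural_connectivity(igraph::make_star(4,
                                                      mode = "undirected")),
               log((exp(sqrt(3)) + exp(-sqrt(3)) + 2) / 4),
               tolerance = 1e-10)

  set.seed(83)
  for (i in 1:100) {
    A <- random_adjacency(7, p = 0.5, seed = i + 500)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::ecount(g) == 0) next
    nc0 <- natural_connectivity(g)
    e <- sample(igraph::ecount(g), 1)
    expect_lte(natural_connectivity(igraph::delete_edges(g, e)),
               nc0 + 1e-12)
  }
})

test_that("robustness curves start intact and follow closed forms", {
  k10 <- igraph::make_full_graph(10)
  curve <- robustness_curve(k10, "degree_descending", max_fraction = 0.1,
                            steps = 2)
  expect_equal(curve$nc_mean[1], natural_connectivity(k10))
  k9_expected <- log((exp(8) + 8 * exp(-1)) / 9)
  expect_equal(curve$nc_mean[2], k9_expected, tolerance = 1e-10)

  rnd <- robustness_curve(k10, "random", max_fraction = 0.1, steps = 2,
                          reps = 5, seed = 3)
  expect_equal(rnd$nc_mean[2], k9_expected, tolerance = 1e-10) # symmetric
  expect_identical(robustness_curve(k10, "random", max_fraction = 0.5,
                                    steps = 3, reps = 5, seed = 7),
                   robustness_curve(k10, "random", max_fraction = 0.5,
                                    steps = 3, reps = 5, seed = 7))
  expect_error(robustness_curve(k10, "random", max_fraction = 1), "< 1")
})

test_that("louvain modularity recovers planted structure", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(5))
  mod <- modularity_partition(two_cliques, seed = 1)
  expect_equal(mod$modularity, 0.5, tolerance = 1e-10)
  expect_equal(mod$n_modules, 2)
  expect_length(unique(mod$membership[1:5]), 1)
  expect_length(unique(mod$membership[6:10]), 1)

  k6 <- modularity_partition(igraph::make_full_graph(6), seed = 1)
  expect_equal(k6$modularity, 0)
  expect_error(modularity_partition(igraph::make_empty_graph(3,
                                                             directed = FALSE)),
               "no edges")

  set.seed(91)
  for (i in 1:10) {
    g <- igraph::sample_gnm(15, 25)
    q <- modularity_partition(g, seed = i)$modularity
    expect_gte(q, -0.5)
    expect_lte(q, 1)
  }
})

test_that("edge census counts by label pair and conserves edges", {
  edges <- data.frame(
    otu_a = c("A1", "A1", "B1"),
    otu_b = c("A2", "B1", "B2"),
    rho = c(0.9, -0.9, 0.85),
    p = c(0, 0, 0),
    sign = c("positive", "negative", "positive")
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- structure(list(graph = g, edges = edges,
                        nodes = data.frame(otu_id = c("A1", "A2", "B1", "B2")),
                        n_tested = 4, n_isolated = 0),
                   class = "co_network")
  labels <- c(A1 = "grpA", A2 = "grpA", B1 = "grpB", B2 = "grpB")
  cen <- edge_census(net, labels)
  row <- function(a, b) cen[cen$label_a == a & cen$label_b == b, ]
  expect_equal(row("grpA", "grpA")$positive, 1)
  expect_equal(row("grpA", "grpA")$negative, 0)
  expect_equal(row("grpB", "grpB")$positive, 1)
  expect_equal(row("grpA", "grpB")$negative, 1)
  expect_equal(sum(cen$positive) + sum(cen$negative), nrow(edges))

  all_one <- edge_census(net, stats::setNames(rep("x", 4), names(labels)))
  expect_equal(all_one$positive + all_one$negative, 3)
})
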