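test_that("prevalence and abundance rules are both enforced, with ceiling", {
  # 10 samples: prevalence threshold is ceiling(0.3 * 10) = 3 samples
  m <- matrix(0, 10, 6)
  m[, 1] <- c(rep(11, 9), 0)        # 99 reads, 9/10 samples -> fails reads
  m[1:2, 2] <- 500                  # 1000 reads, 2/10 samples -> fails prevalence
  m[1:3, 3] <- c(40, 40, 40)        # 120 reads, 3/10 samples -> passes (boundary)
  m[, 4] <- 10                      # 100 reads, 10/10 -> passes (boundary reads)
  m[1:5, 5] <- c(50, 20, 20, 9, 1)  # 100 reads, 5/10 -> passes
  m[1:2, 6] <- c(60, 39)            # 99 reads and 2/10 -> fails both
  tbl <- make_counts_tbl(m, otus = paste0("o", 1:6))
  kept <- prevalence_abundance_filter(tbl, network_config())
  expect_setequal(setdiff(names(kept), "sample_id"), c("o3", "o4", "o5"))
  expect_error(
    prevalence_abundance_filter(tbl, network_config(min_total_reads = 1e6)),
    "no OTU"
  )
})

test_that("CLR rows are centered and match hand arithmetic", {
  expect_true(all(clr_transform(make_counts_tbl(rbind(c(4, 4, 4, 4)))) == 0))
  x <- clr_transform(make_counts_tbl(rbind(c(1, 9))), pseudocount = 1)
  expect_equal(as.numeric(x), c(log(2) - (log(2) + log(10)) / 2,
                                log(10) - (log(2) + log(10)) / 2),
               tolerance = 1e-12)
  r <- random_counts_tbl(5, 12, seed = 30)
  expect_true(all(abs(rowSums(clr_transform(r))) < 1e-12))
  # near scale invariance at large counts: doubling a sample's reads barely
  # moves its CLR profile (pseudocount effect only)
  big <- random_counts_tbl(4, 10, lambda = 5000, seed = 31)
  m2 <- as.matrix(big[, -1]); m2[1, ] <- m2[1, ] * 2
  expect_equal(clr_transform(big)[1, ],
               clr_transform(make_counts_tbl(m2))[1, ], tolerance = 1e-3)
})

test_that("the penalty path starts empty and strong pairs enter first", {
  withr::with_seed(40, {
    z <- stats::rnorm(60)
    X <- cbind(z + stats::rnorm(60, 0, 0.1), z + stats::rnorm(60, 0, 0.1),
               matrix(stats::rnorm(60 * 4), 60, 4))
  })
  colnames(X) <- paste0("v", 1:6)
  cfg <- network_config(nlambda = 15)
  path <- mb_neighborhood_path(X, cfg)
  # lambda_max selects nothing anywhere
  expect_equal(sum(path$adjacency[, , 1]), 0)
  # the planted pair is the first edge on the path
  entry <- apply(path$adjacency, 3, function(a) sum(a & upper.tri(a)))
  first <- min(which(entry > 0))
  expect_true(path$adjacency["v1", "v2", first])
  expect_equal(sum(path$adjacency[, , first] & upper.tri(diag(6))), 1)
})

test_that("a planted chain graph is recovered exactly at the selected lambda", {
  p <- 10; n <- 200
  omega <- diag(p)
  for (i in 1:(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -0.5
  sigma <- solve(omega)
  withr::with_seed(41, {
    X <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  })
  colnames(X) <- paste0("v", 1:p)
  cfg <- network_config(seed = 41)
  lambda <- aquacomm:::.lambda_path(X, cfg$nlambda, cfg$lambda_min_ratio)
  path <- mb_neighborhood_path(X, cfg, lambda = lambda)
  st <- stars_confidence(X, cfg, lambda = lambda)
  adj <- path$adjacency[, , st$lambda_index]
  got <- which(adj & upper.tri(adj), arr.ind = TRUE)
  got_keys <- paste(got[, 1], got[, 2])
  want_keys <- paste(1:(p - 1), 2:p)
  expect_setequal(got_keys, want_keys)
  # true-edge confidence dominates non-edge confidence
  conf <- st$confidence
  truth <- matrix(FALSE, p, p); truth[cbind(1:(p - 1), 2:p)] <- TRUE
  truth <- truth | t(truth)
  expect_gt(mean(conf[truth & upper.tri(conf)]),
            mean(conf[!truth & upper.tri(conf)]))
  expect_true(all(conf >= 0 & conf <= 1))
})

test_that("edge filtering keeps only strictly positive, high-confidence edges", {
  edges <- tibble::tibble(
    from = c("a", "b", "c", "d"),
    to = c("b", "c", "d", "e"),
    coefficient = c(-0.3, 0.2, 0.2, 0.4),
    confidence = c(0.9, 0.5, 0.51, 0.8)
  )
  kept <- filter_network(edges, network_config())
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$from, c("c", "d"))
})

test_that("greedy modularity separates disconnected cliques and planted blocks", {
  clique_edges <- tibble::tibble(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to = c("a2", "a3", "a3", "b2", "b3", "b3")
  )
  cl <- greedy_modularity_clusters(clique_edges)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(length(unique(cl$membership[c("a1", "a2", "a3")])), 1)
  expect_gt(cl$modularity, 0)
  # planted two-block graph
  withr::with_seed(52, {
    n <- 30
    block <- rep(1:2, each = n / 2)
    pairs <- t(utils::combn(n, 2))
    pp <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], 0.5, 0.02)
    sel <- stats::runif(nrow(pairs)) < pp
    edges <- tibble::tibble(from = paste0("n", pairs[sel, 1]),
                            to = paste0("n", pairs[sel, 2]))
  })
  cl2 <- greedy_modularity_clusters(edges)
  got <- cl2$membership[paste0("n", 1:n)]
  # exact recovery up to label switching
  expect_equal(length(unique(got[block == 1])), 1)
  expect_equal(length(unique(got[block == 2])), 1)
  expect_false(got[1] == got[n])
})

test_that("degree tables satisfy the handshake identity", {
  tri <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"))
  dd <- degree_distribution_table(tri)
  expect_equal(dd$degrees$degree, c(2, 2, 2))
  star <- tibble::tibble(from = rep("hub", 5), to = paste0("leaf", 1:5))
  ds <- degree_distribution_table(star)
  expect_equal(sort(ds$degrees$degree, decreasing = TRUE), c(5, 1, 1, 1, 1, 1))
  withr::with_seed(53, {
    pairs <- t(utils::combn(12, 2))
    sel <- stats::runif(nrow(pairs)) < 0.3
    e <- tibble::tibble(from = paste0("v", pairs[sel, 1]),
                        to = paste0("v", pairs[sel, 2]))
  })
  de <- degree_distribution_table(e)
  expect_equal(sum(de$degrees$degree), 2 * nrow(e))
})

test_that("the full network chain recovers planted structure on one scenario", {
  ns <- network_scenario(seed = 1)
  net <- infer_cooccurrence_network(ns$counts, network_config(seed = 1),
                                    taxonomy = ns$bundle$taxonomy)
  planted <- edge_key(ns$pg$from, ns$pg$to)
  found <- edge_key(net$edges$from, net$edges$to)
  expect_gte(mean(found %in% planted), 0.7)
  expect_gte(mean(planted %in% found), 0.8)
  # hubs are non-isolated
  hubs <- c("Otu0001", "Otu0002")
  expect_true(all(net$nodes$degree[net$nodes$otu_id %in% hubs] > 0))
  # taxonomy columns flow into the node table
  expect_true("phylum" %in% names(net$nodes))
  # planted co-varying chain members share a cluster
  chain1 <- sprintf("Otu%04d", 15:19)
  cl <- net$nodes$cluster[net$nodes$otu_id %in% chain1]
  expect_equal(length(unique(cl)), 1)
})

test_that("neighbor composition comparison is exact for small groups", {
  edges <- tibble::tibble(
    from = c("p1", "p1", "p2", "q1", "q1", "q2"),
    to   = c("x1", "x2", "x1", "y1", "y2", "y1")
  )
  nodes <- unique(c(edges$from, edges$to))
  tax <- tibble::tibble(otu_id = nodes,
                        phylum = ifelse(grepl("^[xy]", nodes), "Other", "Focal"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  net <- structure(list(graph = g), class = "confidence_network")
  r <- neighbor_composition_test(net, c("p1", "p2"), c("q1", "q2"),
                                 tax, "phylum", "Other")
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1) # symmetric construction
  expect_error(
    neighbor_composition_test(net, character(0), c("q1"), tax, "phylum", "Other"),
    "group"
  )
})
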