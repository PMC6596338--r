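#' Configuration for co-occurrence network inference
#'
#' Defaults follow the study settings: OTUs kept only with >= 100 total reads
#' and presence in >= 30% of samples, a 20-point lambda path down to 1% of
#' lambda-max, 50 StARS subsamples, and a strict confidence cutoff of 0.5 on
#' positive edges.
#'
#' @param min_total_reads minimum summed reads per OTU across all samples.
#' @param min_prevalence minimum fraction of samples an OTU must be present
#'   in (threshold count is the ceiling of `min_prevalence * n_samples`).
#' @param pseudocount added to counts before the log in the CLR transform.
#' @param nlambda number of penalty values on the path.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda-max.
#' @param stars_reps number of StARS subsamples.
#' @param stars_threshold StARS average-instability threshold.
#' @param stars_subsample_size subsample size; `NULL` (default) uses
#'   `min(floor(10 * sqrt(n)), floor(0.632 * n))`.
#' @param confidence_cutoff edges are retained only with confidence strictly
#'   above this value.
#' @param seed integer seed driving all subsampling.
#' @return a list of class `network_config`.
#' @export
network_config <- function(min_total_reads = 100, min_prevalence = 0.30,
                           pseudocount = 1, nlambda = 20,
                           lambda_min_ratio = 1e-2, stars_reps = 50,
                           stars_threshold = 0.05, stars_subsample_size = NULL,
                           confidence_cutoff = 0.5, seed = 1) {
  stopifnot(min_total_reads > 0, min_prevalence > 0, min_prevalence <= 1,
            nlambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            stars_reps >= 2, stars_threshold > 0, confidence_cutoff >= 0)
  structure(as.list(environment()), class = "network_config")
}

#' Prevalence and abundance filter for network input
#'
#' Keeps an OTU only if it is represented by at least `min_total_reads`
#' reads summed over all samples AND present (>= 1 read) in at least
#' `ceiling(min_prevalence * n_samples)` samples.
#'
#' @param tbl OTU count tibble.
#' @param cfg a [network_config()].
#' @return the filtered count tibble; errors if nothing survives.
#' @export
prevalence_abundance_filter <- function(tbl, cfg = network_config()) {
  m <- otu_matrix(tbl)
  need_n <- ceiling(cfg$min_prevalence * nrow(m))
  keep <- colSums(m) >= cfg$min_total_reads & colSums(m > 0) >= need_n
  if (!any(keep)) rlang::abort("no OTU passes the prevalence/abundance filter")
  otu_tibble(m[, keep, drop = FALSE])
}

#' Centred log-ratio transform
#'
#' Per sample: `clr = log(count + pseudocount) - mean(log(count +
#' pseudocount))`, rendering compositional counts amenable to
#' covariance-based inference. Output rows sum to zero.
#'
#' @param tbl OTU count tibble (or numeric matrix).
#' @param pseudocount added before the log (default 1).
#' @return numeric matrix (samples x OTUs) of CLR values.
#' @export
clr_transform <- function(tbl, pseudocount = 1) {
  m <- if (is.data.frame(tbl)) otu_matrix(tbl) else tbl
  lx <- log(m + pseudocount)
  lx - rowMeans(lx)
}

# shared log-spaced lambda path from lambda_max (empty graph) downwards
.lambda_path <- function(X, nlambda, lambda_min_ratio) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- abs(crossprod(Xc)) / n
  diag(S) <- 0
  lmax <- max(S)
  if (lmax <= 0) rlang::abort("degenerate data: no covariance between any variables")
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Meinshausen-Buhlmann neighborhood selection along a lambda path
#'
#' For each node, an L1-penalized linear regression of its CLR profile on
#' all other nodes (via glmnet), solved on a common log-spaced path of
#' `nlambda` penalties from lambda-max (the smallest penalty selecting
#' nothing anywhere) down to `lambda_max * lambda_min_ratio`. An undirected
#' edge exists at a given lambda if either direction selects it (union
#' rule); its coefficient is the mean of the available directed
#' coefficients.
#'
#' @param X CLR matrix (samples x OTUs); needs >= 4 samples and >= 2 OTUs.
#' @param cfg a [network_config()].
#' @param lambda optional explicit penalty path (decreasing); computed from
#'   the data by default.
#' @return list of class `mb_path`: `lambda` (the path), `adjacency`
#'   (p x p x nlambda logical array) and `coefficient` (p x p x nlambda,
#'   symmetrized means).
#' @export
mb_neighborhood_path <- function(X, cfg = network_config(), lambda = NULL) {
  if (nrow(X) < 4) rlang::abort("need at least 4 samples")
  p <- ncol(X)
  if (p < 2) rlang::abort("need at least 2 OTUs")
  if (is.null(lambda)) lambda <- .lambda_path(X, cfg$nlambda, cfg$lambda_min_ratio)
  nl <- length(lambda)
  beta <- array(0, dim = c(p, p, nl))
  for (j in seq_len(p)) {
    fit <- tryCatch(
      glmnet::glmnet(X[, -j, drop = FALSE], X[, j], family = "gaussian",
                     lambda = lambda, standardize = FALSE, intercept = TRUE),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- as.matrix(stats::coef(fit))[-1, , drop = FALSE] # drop intercept
    # glmnet may return fewer lambdas than requested on early exit
    got <- match(signif(fit$lambda, 10), signif(lambda, 10))
    beta[setdiff(seq_len(p), j), j, got[!is.na(got)]] <-
      cf[, !is.na(got), drop = FALSE]
  }
  adjacency <- array(FALSE, dim = dim(beta))
  coefficient <- array(0, dim = dim(beta))
  for (l in seq_len(nl)) {
    B <- beta[, , l]
    sel <- (B != 0) | (t(B) != 0)
    ndir <- (B != 0) + (t(B) != 0)
    co <- (B + t(B)) / pmax(ndir, 1)
    co[!sel] <- 0
    adjacency[, , l] <- sel
    coefficient[, , l] <- co
  }
  dimnames(adjacency) <- dimnames(coefficient) <-
    list(colnames(X), colnames(X), NULL)
  structure(list(lambda = lambda, adjacency = adjacency,
                 coefficient = coefficient),
            class = "mb_path")
}

#' StARS: stability-based penalty selection and edge confidence
#'
#' Draws `stars_reps` subsamples of the rows without replacement, refits the
#' neighborhood-selection path on each, and measures per-edge selection
#' frequencies. The selected lambda is the densest penalty whose average
#' edge instability `2 * f * (1 - f)` (monotonized along the path from
#' sparse to dense) stays at or below `stars_threshold`. Confidence of an
#' edge is its selection frequency across subsamples at the selected lambda.
#'
#' @param X CLR matrix (samples x OTUs).
#' @param cfg a [network_config()]; `cfg$seed` drives subsampling.
#' @param lambda optional explicit path shared with the full-data fit.
#' @return list of class `stars_result`: `lambda_index`, `lambda`,
#'   `confidence` (p x p symmetric matrix), `instability` (raw per-lambda),
#'   `instability_monotone`, `subsample_size`, `subsamples` (list of row
#'   index sets).
#' @export
stars_confidence <- function(X, cfg = network_config(), lambda = NULL) {
  n <- nrow(X)
  if (is.null(lambda)) lambda <- .lambda_path(X, cfg$nlambda, cfg$lambda_min_ratio)
  b <- cfg$stars_subsample_size %||% min(floor(10 * sqrt(n)), floor(0.632 * n))
  if (b < 4) rlang::abort("StARS subsample size below 4")
  p <- ncol(X)
  nl <- length(lambda)
  counts <- array(0, dim = c(p, p, nl))
  subsamples <- with_seed_opt(cfg$seed,
    lapply(seq_len(cfg$stars_reps), function(r) sort(sample.int(n, b))))
  for (rows in subsamples) {
    fit <- mb_neighborhood_path(X[rows, , drop = FALSE], cfg, lambda = lambda)
    counts <- counts + fit$adjacency
  }
  freq <- counts / cfg$stars_reps
  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(seq_len(nl), function(l) {
    f <- freq[, , l][ut]
    mean(2 * f * (1 - f))
  }, numeric(1))
  mono <- cummax(instability)
  ok <- which(mono <= cfg$stars_threshold)
  lambda_index <- if (length(ok)) max(ok) else 1L
  conf <- freq[, , lambda_index]
  dimnames(conf) <- list(colnames(X), colnames(X))
  structure(list(lambda_index = lambda_index, lambda = lambda[lambda_index],
                 lambda_path = lambda, confidence = conf,
                 instability = instability, instability_monotone = mono,
                 subsample_size = b, subsamples = subsamples),
            class = "stars_result")
}

# edge tibble from a path fit at one lambda index plus a confidence matrix
.edge_table <- function(path, lambda_index, confidence) {
  adj <- path$adjacency[, , lambda_index]
  co <- path$coefficient[, , lambda_index]
  ids <- rownames(adj)
  sel <- which(adj & upper.tri(adj), arr.ind = TRUE)
  tibble::tibble(
    from = ids[sel[, 1]],
    to = ids[sel[, 2]],
    coefficient = co[sel],
    confidence = confidence[sel]
  )
}

#' Filter edges to positive, high-confidence interactions
#'
#' Retains edges with strictly positive coefficient and confidence strictly
#' above `cfg$confidence_cutoff`.
#'
#' @param edges tibble with `from`, `to`, `coefficient`, `confidence`.
#' @param cfg a [network_config()].
#' @return the filtered edge tibble.
#' @export
filter_network <- function(edges, cfg = network_config()) {
  dplyr::filter(edges, .data$coefficient > 0,
                .data$confidence > cfg$confidence_cutoff)
}

#' Infer a positive co-occurrence network with stability confidence
#'
#' The full chain of the network module: prevalence/abundance filtering, CLR
#' transform, Meinshausen-Buhlmann neighborhood selection along a lambda
#' path, StARS penalty selection with per-edge confidence, filtering to
#' positive high-confidence edges, and greedy-modularity clustering of the
#' result.
#'
#' @param tbl OTU count tibble (merged whole-community samples).
#' @param cfg a [network_config()].
#' @param taxonomy optional taxonomy tibble; lineage columns are attached to
#'   the node table.
#' @return an object of class `confidence_network`: list with `nodes`
#'   (tibble: `otu_id`, `degree`, `cluster`, taxonomy columns), `edges`
#'   (tibble: `from`, `to`, `coefficient`, `confidence`), `all_edges`
#'   (pre-filter edge table at the selected lambda), `stars`, `modularity`,
#'   `config`.
#' @export
infer_cooccurrence_network <- function(tbl, cfg = network_config(),
                                       taxonomy = NULL) {
  kept <- prevalence_abundance_filter(tbl, cfg)
  X <- clr_transform(kept, cfg$pseudocount)
  lambda <- .lambda_path(X, cfg$nlambda, cfg$lambda_min_ratio)
  path <- mb_neighborhood_path(X, cfg, lambda = lambda)
  st <- stars_confidence(X, cfg, lambda = lambda)
  all_edges <- .edge_table(path, st$lambda_index, st$confidence)
  edges <- filter_network(all_edges, cfg)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = colnames(X))
  cl <- greedy_modularity_clusters(g)
  deg <- igraph::degree(g)
  nodes <- tibble::tibble(
    otu_id = colnames(X),
    degree = as.integer(deg[colnames(X)]),
    cluster = cl$membership[colnames(X)]
  )
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes, taxonomy, by = "otu_id")
  }
  structure(list(nodes = nodes, edges = edges, all_edges = all_edges,
                 stars = st, modularity = cl$modularity, graph = g,
                 config = cfg),
            class = "confidence_network")
}

#' Greedy modularity clustering
#'
#' Agglomerative modularity maximization (merging the community pair with
#' the largest modularity gain until none is positive), via
#' `igraph::cluster_fast_greedy`. Isolated nodes end up in singleton
#' clusters. Edges are treated as unweighted.
#'
#' @param x a `confidence_network`, an igraph graph, or an edge tibble with
#'   `from`/`to` columns.
#' @return list with `membership` (named integer vector) and `modularity`
#'   of the returned partition.
#' @export
greedy_modularity_clusters <- function(x) {
  g <- if (inherits(x, "igraph")) {
    x
  } else if (inherits(x, "confidence_network")) {
    x$graph
  } else {
    igraph::graph_from_data_frame(x[, c("from", "to")], directed = FALSE)
  }
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  membership <- igraph::membership(cl)
  list(membership = setNames(as.integer(membership), names(membership)),
       modularity = igraph::modularity(g, membership))
}

#' Per-node degrees and the degree histogram
#'
#' @param x a `confidence_network` or edge tibble.
#' @return list with `degrees` (tibble `otu_id`, `degree`) and `histogram`
#'   (tibble `degree`, `n_nodes`); the handshake identity
#'   `sum(degree) == 2 * n_edges` holds.
#' @export
degree_distribution_table <- function(x) {
  if (inherits(x, "confidence_network")) {
    degs <- tibble::tibble(otu_id = x$nodes$otu_id, degree = x$nodes$degree)
  } else {
    g <- igraph::graph_from_data_frame(x[, c("from", "to")], directed = FALSE)
    d <- igraph::degree(g)
    degs <- tibble::tibble(otu_id = names(d), degree = as.integer(d))
  }
  hist <- degs |>
    dplyr::count(.data$degree, name = "n_nodes") |>
    dplyr::arrange(.data$degree)
  list(degrees = degs, histogram = hist)
}

#' Compare neighbor composition between two node groups
#'
#' For every node, computes the fraction of its first-degree neighbors
#' carrying `label` (a value of the taxonomy column `rank`), then compares
#' the two node groups' fractions with a Mann-Whitney U test (exact for
#' small groups, tie-corrected normal approximation otherwise).
#'
#' @param network a `confidence_network`.
#' @param group_a,group_b character vectors of node (OTU) ids; nodes without
#'   neighbors are skipped.
#' @param taxonomy taxonomy tibble.
#' @param rank taxonomy column holding `label`.
#' @param label the lineage value whose neighbor fraction is compared
#'   (e.g. a focal phylum).
#' @return list with `u`, `p_value`, the per-node `fractions` tibble, and
#'   group sizes.
#' @export
neighbor_composition_test <- function(network, group_a, group_b, taxonomy,
                                      rank, label) {
  g <- network$graph
  lab <- setNames(taxonomy[[rank]], taxonomy$otu_id)
  frac_of <- function(v) {
    nb <- names(igraph::neighbors(g, v))
    if (!length(nb)) return(NA_real_)
    mean(lab[nb] == label, na.rm = TRUE)
  }
  all_nodes <- igraph::V(g)$name
  fa <- vapply(intersect(group_a, all_nodes), frac_of, numeric(1))
  fb <- vapply(intersect(group_b, all_nodes), frac_of, numeric(1))
  fa <- fa[!is.na(fa)]; fb <- fb[!is.na(fb)]
  if (!length(fa) || !length(fb)) rlang::abort("a group has no connected nodes")
  mw <- mann_whitney_u(fa, fb)
  fractions <- dplyr::bind_rows(
    tibble::tibble(otu_id = names(fa), group = "a", fraction = unname(fa)),
    tibble::tibble(otu_id = names(fb), group = "b", fraction = unname(fb))
  )
  c(mw, list(fractions = fractions))
}

#' @method print confidence_network
#' @export
print.confidence_network <- function(x, ...) {
  cat("Positive co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "high-confidence edges\n")
  cat("  selected lambda:", signif(x$stars$lambda, 4),
      "(index", x$stars$lambda_index, "of", length(x$stars$lambda_path), ")\n")
  cat("  clusters:", length(unique(x$nodes$cluster)),
      " modularity:", round(x$modularity, 3), "\n")
  invisible(x)
}

#' @export
tidy.confidence_network <- function(x, ...) {
  x$edges
}

#' @export
glance.confidence_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_clusters = length(unique(x$nodes$cluster[x$nodes$degree > 0])),
    modularity = x$modularity,
    lambda = x$stars$lambda,
    mean_confidence = mean(x$edges$confidence)
  )
}

#' @export
autoplot.confidence_network <- function(object, ...) {
  hist <- degree_distribution_table(object)$histogram
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "node degree", y = "number of OTUs") +
    ggplot2::theme_minimal()
}
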