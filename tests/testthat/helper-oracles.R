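# fixtures and independent brute-force oracles used across the suite

make_counts_tbl <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(m)))
  if (is.null(otus)) otus <- paste0("Otu", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  tibble::as_tibble(m, rownames = "sample_id")
}

random_counts_tbl <- function(n_samples, n_otus, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus)
    m[1, 1] <- m[1, 1] + 1 # guard against an all-zero OTU column
    make_counts_tbl(m)
  })
}

# patristic distances by explicit root-path walking (independent of
# cophenetic): d(i,j) = depth(i) + depth(j) - 2 * depth(lca)
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- numeric(max(tree$edge))
  edge_len[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(v) {
    p <- v
    while (v != root) {
      v <- parent[v]
      p <- c(p, v)
    }
    p
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(paths[[i]], paths[[j]])
      d <- sum(edge_len[setdiff(paths[[i]], shared)]) +
        sum(edge_len[setdiff(paths[[j]], shared)])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# naive two-loop abundance-weighted beta-MNTD
bmntd_oracle <- function(rel_k, rel_m, D) {
  rel_k <- rel_k[rel_k > 0]
  rel_m <- rel_m[rel_m > 0]
  s1 <- 0
  for (i in names(rel_k)) {
    s1 <- s1 + rel_k[[i]] * min(vapply(names(rel_m), function(j) D[i, j], numeric(1)))
  }
  s2 <- 0
  for (j in names(rel_m)) {
    s2 <- s2 + rel_m[[j]] * min(vapply(names(rel_k), function(i) D[j, i], numeric(1)))
  }
  0.5 * (s1 + s2)
}

# O(n^3) UPGMA: returns sorted merge heights
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_between <- function(a, b) mean(d[a, b])
  while (length(active) > 1) {
    best <- c(1, 2)
    best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j) {
          dd <- dist_between(active[[i]], active[[j]])
          if (dd < best_d) {
            best_d <- dd
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  sort(heights)
}

# exact two-sided Mann-Whitney p by enumerating group assignments
mwu_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12))
}

# exact two-sided Spearman p by enumerating all n! permutations
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho_of <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  rho_obs <- rho_of(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  all_rho <- vapply(perms(ry), function(p) rho_of(rx, p), numeric(1))
  list(rho = rho_obs, p = mean(abs(all_rho) >= abs(rho_obs) - 1e-12))
}

# planted-graph scenario shared by network tests
network_scenario <- function(seed, effect = 0.9, n_timepoints = 5) {
  otus <- sprintf("Otu%04d", 1:60)
  pg <- planted_association_graph(otus, effect = effect)
  cfg <- scenario_config(
    seed = seed, regime = "neutral", n_otus = 60,
    wells = sprintf("W%02d", 1:10),
    well_distances_km = seq(0.5, 5, length.out = 10),
    n_timepoints = n_timepoints, read_depth = 1e5,
    sad_sdlog = 1, planted_graph = pg
  )
  sc <- suppressMessages(generate_scenario(cfg))
  gw <- sc$bundle$bulk_water[grepl("^W", sc$bundle$bulk_water$sample_id), ]
  list(pg = pg, counts = gw, bundle = sc$bundle)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
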