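#' Patristic distance matrix of a tree's tips
#'
#' Sum of branch lengths along the tip-to-tip path, for every pair of tips.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    rlang::abort("tree must have complete branch lengths")
  }
  ape::cophenetic.phylo(tree)
}

#' Bray-Curtis dissimilarity
#'
#' For relative abundances (each vector summing to 1) this reduces to
#' `1 - sum(pmin(x, y))`; for raw counts the general
#' `1 - 2*sum(pmin) / (sum(x) + sum(y))` form is used. Vectors are aligned on
#' the union of their names when named.
#'
#' @param x,y non-negative numeric vectors.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    al <- align_union(x, y)
    x <- al$x; y <- al$y
  }
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# beta-MNTD on index/weight form: wk, wm are weights summing to 1 over the
# tips at positions ik, im of distance matrix D
.beta_mntd_idx <- function(ik, im, wk, wm, D) {
  d <- D[ik, im, drop = FALSE]
  near_k <- d[cbind(seq_along(ik), max.col(-d, ties.method = "first"))]
  near_m <- d[cbind(max.col(-t(d), ties.method = "first"), seq_along(im))]
  0.5 * (sum(wk * near_k) + sum(wm * near_m))
}

#' Abundance-weighted beta mean-nearest-taxon distance
#'
#' Pairwise phylogenetic turnover between two communities:
#' `0.5 * ( sum_i w_k(i) min_j d(i,j) + sum_j w_m(j) min_i d(j,i) )`,
#' where the minima run over the taxa detected in the other community. Taxa
#' present in both contribute a nearest distance of zero.
#'
#' @param rel_k,rel_m named relative-abundance vectors (each summing to 1
#'   over its detected OTUs; zeros allowed and ignored).
#' @param D patristic distance matrix covering all detected OTUs.
#' @return non-negative scalar.
#' @export
beta_mntd <- function(rel_k, rel_m, D) {
  rel_k <- rel_k[rel_k > 0]; rel_m <- rel_m[rel_m > 0]
  if (!length(rel_k) || !length(rel_m)) rlang::abort("empty community")
  ik <- match(names(rel_k), rownames(D))
  im <- match(names(rel_m), rownames(D))
  if (anyNA(ik) || anyNA(im)) rlang::abort("community OTUs missing from distance matrix")
  .beta_mntd_idx(ik, im, rel_k, rel_m, D)
}

#' Beta nearest-taxon index (tip-shuffling null)
#'
#' Standardized effect size of the observed beta-MNTD against a null in which
#' OTU identities are shuffled across the tips of the phylogeny (i.e. the
#' rows/columns of the patristic matrix are jointly permuted over the full
#' analyzed OTU pool). `beta_nti = (obs - mean(null)) / sd(null)` with the
#' `n - 1` standard deviation. Values above 2 indicate variable selection,
#' below -2 homogeneous selection.
#'
#' @inheritParams beta_mntd
#' @param n_reps number of tip shuffles (study default 999).
#' @param seed optional integer seed.
#' @return a list with `beta_mntd`, `null_mean`, `null_sd`, `beta_nti`
#'   (`NA` with a warning when the null distribution is degenerate), and
#'   `n_reps`.
#' @export
beta_nti <- function(rel_k, rel_m, D, n_reps = 999, seed = NULL) {
  if (n_reps < 2) rlang::abort("n_reps must be >= 2")
  rel_k <- rel_k[rel_k > 0]; rel_m <- rel_m[rel_m > 0]
  ik <- match(names(rel_k), rownames(D))
  im <- match(names(rel_m), rownames(D))
  if (anyNA(ik) || anyNA(im)) rlang::abort("community OTUs missing from distance matrix")
  obs <- .beta_mntd_idx(ik, im, rel_k, rel_m, D)
  npool <- nrow(D)
  nulls <- with_seed_opt(seed, vapply(seq_len(n_reps), function(r) {
    perm <- sample.int(npool)
    .beta_mntd_idx(perm[ik], perm[im], rel_k, rel_m, D)
  }, numeric(1)))
  mu <- mean(nulls); s <- stats::sd(nulls)
  if (s == 0) {
    rlang::warn("degenerate null distribution (sd = 0); beta_nti undefined")
    bnti <- NA_real_
  } else {
    bnti <- (obs - mu) / s
  }
  list(beta_mntd = obs, null_mean = mu, null_sd = s, beta_nti = bnti,
       n_reps = n_reps)
}

# integerize a relative-abundance vector to counts summing to `total`
# (largest-remainder rounding)
.largest_remainder <- function(rel, total) {
  raw <- rel * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

# assemble one null community: draw `richness` members with probability
# proportional to metacommunity occurrence frequency, give each member one
# read, distribute the remaining reads multinomially proportional to
# metacommunity relative abundance among members
.rc_null_community <- function(richness, total, p_occ, p_ab) {
  members <- sample.int(length(p_occ), richness, replace = FALSE, prob = p_occ)
  reads <- rep.int(1L, richness)
  extra <- total - richness
  if (extra > 0) {
    reads <- reads + as.integer(rmultinom(1, extra, p_ab[members]))
  }
  list(members = members, reads = reads)
}

.bc_null_pair <- function(a, b, n_otus) {
  xa <- numeric(n_otus); xb <- numeric(n_otus)
  xa[a$members] <- a$reads; xb[b$members] <- b$reads
  1 - 2 * sum(pmin(xa, xb)) / (sum(xa) + sum(xb))
}

#' Rescaled Raup-Crick index on Bray-Curtis distance
#'
#' Compares the observed Bray-Curtis dissimilarity of two communities with a
#' null distribution generated under the hypothesis of identical species
#' composition: each replicate assembles two null communities preserving each
#' sample's observed richness and total reads, drawing membership with
#' probability proportional to each OTU's occurrence frequency across the
#' metacommunity and assigning reads proportionally to metacommunity relative
#' abundance. With `P` the fraction of null dissimilarities below the
#' observed one (ties at half weight), `rc_bray = 2 * (P - 0.5)`; values
#' above 0.95 indicate dispersal limitation, below -0.95 homogenizing
#' dispersal (when selection is weak).
#'
#' @param counts_k,counts_m named integer count vectors (post-rarefaction).
#' @param metacommunity OTU count tibble (or matrix) defining occurrence
#'   frequencies and relative abundances; must include both samples' OTUs.
#' @param n_reps number of null replicates (study default 999).
#' @param seed optional integer seed.
#' @return scalar in `[-1, 1]`.
#' @export
rc_bray <- function(counts_k, counts_m, metacommunity, n_reps = 999, seed = NULL) {
  meta <- if (is.data.frame(metacommunity)) otu_matrix(metacommunity) else metacommunity
  otus <- colnames(meta)
  miss <- setdiff(c(names(counts_k)[counts_k > 0], names(counts_m)[counts_m > 0]), otus)
  if (length(miss)) rlang::abort("sample OTUs missing from metacommunity")
  p_occ <- colSums(meta > 0) / nrow(meta)
  p_ab <- colSums(meta) / sum(meta)
  expand <- function(x) {
    v <- setNames(numeric(length(otus)), otus)
    v[names(x)] <- x
    v
  }
  xk <- expand(counts_k); xm <- expand(counts_m)
  rich_k <- sum(xk > 0); rich_m <- sum(xm > 0)
  if (rich_k > length(otus) || rich_m > length(otus)) {
    rlang::abort("sample richness exceeds metacommunity OTU count")
  }
  obs <- 1 - 2 * sum(pmin(xk, xm)) / (sum(xk) + sum(xm))
  tot_k <- sum(xk); tot_m <- sum(xm)
  nulls <- with_seed_opt(seed, vapply(seq_len(n_reps), function(r) {
    a <- .rc_null_community(rich_k, tot_k, p_occ, p_ab)
    b <- .rc_null_community(rich_m, tot_m, p_occ, p_ab)
    .bc_null_pair(a, b, length(otus))
  }, numeric(1)))
  eps <- 1e-12
  p_less <- sum(nulls < obs - eps)
  p_tie <- sum(abs(nulls - obs) <= eps)
  P <- (p_less + 0.5 * p_tie) / n_reps
  2 * (P - 0.5)
}

#' Classify the dominant community-assembly process of a sample pair
#'
#' Thresholds follow the standard two-stage null-model scheme: selection is
#' read off the phylogenetic index first (`beta_nti > 2` variable selection,
#' `< -2` homogeneous selection); among stochastic pairs (`|beta_nti| < 2`),
#' `rc_bray > 0.95` indicates dispersal limitation, `< -0.95` homogenizing
#' dispersal, and intermediate values no dominant process.
#'
#' @param beta_nti,rc_bray numeric vectors (recycled to common length).
#' @return character vector of process labels: `variable_selection`,
#'   `homogeneous_selection`, `dispersal_limitation`,
#'   `homogenizing_dispersal`, `undominated`, or `undefined` when either
#'   index is `NA`.
#' @export
classify_assembly <- function(beta_nti, rc_bray) {
  n <- max(length(beta_nti), length(rc_bray))
  beta_nti <- rep_len(beta_nti, n); rc_bray <- rep_len(rc_bray, n)
  dplyr::case_when(
    is.na(beta_nti) | is.na(rc_bray) ~ "undefined",
    beta_nti > 2 ~ "variable_selection",
    beta_nti < -2 ~ "homogeneous_selection",
    rc_bray > 0.95 ~ "dispersal_limitation",
    rc_bray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
}

#' Pairwise community-assembly analysis
#'
#' Runs the full per-pair chain on a set of samples: optional rarefaction to
#' a common depth, beta-MNTD / beta-NTI against the tip-shuffling null,
#' RC-bray against the taxonomic null, and the five-way process
#' classification. Null randomizations are regenerated independently per pair
#' from substreams of `seed`; pairs are unordered and reported once in
#' lexicographic sample order.
#'
#' @param tbl OTU count tibble (integer counts; either whole-community
#'   samples, or filter-fraction samples together with `metadata`/`qpcr`).
#' @param tree rooted `phylo` tree whose tips cover the table's OTUs.
#' @param samples optional subset of sample ids (default: all).
#' @param depth rarefaction depth (study default 7876); `NULL` skips
#'   rarefaction (counts must then already be comparable).
#' @param n_reps null replicates for both indices (study default 999).
#' @param seed integer seed for all randomness.
#' @param metadata,qpcr optional; when both are given, fraction samples are
#'   rarefied, merged per site and time point via
#'   [merge_sample_fractions()], and the merged relative abundances are
#'   converted back to integer counts summing to `depth` (largest-remainder
#'   rounding) so the taxonomic null can operate on reads.
#' @return a tibble of class `assembly_result` with one row per unordered
#'   sample pair: `sample_1`, `sample_2`, `beta_mntd`, `null_mean`,
#'   `null_sd`, `beta_nti`, `rc_bray`, `process`, `n_reps`, `seed`.
#' @export
assembly_analysis <- function(tbl, tree, samples = NULL, depth = 7876,
                              n_reps = 999, seed = 1, metadata = NULL,
                              qpcr = NULL) {
  if (!is.null(samples)) {
    tbl <- tbl[match(samples, tbl$sample_id), , drop = FALSE]
    if (anyNA(tbl$sample_id)) rlang::abort("requested samples missing from table")
  }
  if (!is.null(depth)) {
    tbl <- rarefy(tbl, depth, seed = substream_seed(seed, 0))
  }
  if (!is.null(metadata) && !is.null(qpcr)) {
    if (is.null(depth)) rlang::abort("fraction merging requires a depth")
    merged <- merge_sample_fractions(tbl, metadata, qpcr)
    m_rel <- otu_matrix(merged)
    counts <- t(apply(m_rel, 1, .largest_remainder, total = depth))
    colnames(counts) <- colnames(m_rel)
    tbl <- otu_tibble(counts[, colSums(counts) > 0, drop = FALSE])
  }
  m <- otu_matrix(tbl)
  validate_bundle(tbl, tree = tree)
  pool <- colnames(m)
  D <- patristic_distances(tree)
  D <- D[pool, pool]
  ids <- sort(rownames(m))
  pairs <- utils::combn(ids, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    s1 <- pairs[1, p]; s2 <- pairs[2, p]
    ck <- m[s1, ]; cm <- m[s2, ]
    rk <- ck / sum(ck); rm_ <- cm / sum(cm)
    bn <- beta_nti(rk, rm_, D, n_reps = n_reps, seed = substream_seed(seed, 2 * p))
    rc <- rc_bray(ck, cm, m, n_reps = n_reps, seed = substream_seed(seed, 2 * p + 1))
    tibble::tibble(
      sample_1 = s1, sample_2 = s2,
      beta_mntd = bn$beta_mntd, null_mean = bn$null_mean, null_sd = bn$null_sd,
      beta_nti = bn$beta_nti, rc_bray = rc,
      process = classify_assembly(bn$beta_nti, rc),
      n_reps = n_reps, seed = seed
    )
  })
  class(res) <- c("assembly_result", class(res))
  res
}

#' @export
tidy.assembly_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "assembly_result")
  out
}

#' @export
glance.assembly_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    mean_beta_nti = mean(x$beta_nti, na.rm = TRUE),
    mean_rc_bray = mean(x$rc_bray, na.rm = TRUE),
    modal_process = names(sort(table(x$process), decreasing = TRUE))[1]
  )
}

#' @export
autoplot.assembly_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rc_bray, y = .data$beta_nti,
                               colour = .data$process)) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-0.95, 0.95), linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(RC[bray]), y = expression(beta * NTI),
                  colour = "process") +
    ggplot2::theme_minimal()
}
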