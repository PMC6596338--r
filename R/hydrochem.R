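#' Spearman correlation profile of taxa against hydrochemical parameters
#'
#' Correlates every entity (taxon or OTU) column of `abund_tbl` with every
#' parameter column of `hydrochem` across samples matched on `sample_id`.
#' Missing values are pairwise-deleted; ties take midranks; two-sided
#' p-values are permutation-exact for small n (see [spearman_test()]).
#' No multiple-testing correction is applied by default, matching the
#' per-test significance convention; set `adjust = "BH"` for
#' Benjamini-Hochberg within the profile.
#'
#' @param abund_tbl relative-abundance tibble (`sample_id` + entity columns).
#' @param hydrochem hydrochemistry tibble (`sample_id` + numeric parameter
#'   columns; `site`/`time_point` columns are ignored).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param min_pairs minimum complete pairs required per cell (default 5).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a tibble of class `correlation_profile` with columns `entity`,
#'   `parameter`, `rho`, `p_value`, `n`, `significant`.
#' @export
spearman_profile <- function(abund_tbl, hydrochem, alpha = 0.05, min_pairs = 5,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  par_cols <- setdiff(names(hydrochem), c("sample_id", "site", "time_point"))
  ent_cols <- setdiff(names(abund_tbl), "sample_id")
  joined <- dplyr::inner_join(abund_tbl, hydrochem[, c("sample_id", par_cols)],
                              by = "sample_id")
  if (!nrow(joined)) rlang::abort("no samples shared between abundance and hydrochemistry tables")
  grid <- tidyr::expand_grid(entity = ent_cols, parameter = par_cols)
  res <- purrr::pmap_dfr(grid, function(entity, parameter) {
    a <- joined[[entity]]; h <- joined[[parameter]]
    ok <- stats::complete.cases(a, h)
    if (sum(ok) < min_pairs) {
      return(tibble::tibble(entity = entity, parameter = parameter,
                            rho = NA_real_, p_value = NA_real_,
                            n = sum(ok), significant = FALSE))
    }
    st <- spearman_test(a[ok], h[ok])
    tibble::tibble(entity = entity, parameter = parameter,
                   rho = st$rho, p_value = st$p_value, n = st$n,
                   significant = !is.na(st$p_value) && st$p_value < alpha)
  })
  if (adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_value) & res$p_value < alpha
  }
  class(res) <- c("correlation_profile", class(res))
  res
}

# entity x parameter matrix of rho values; undefined cells become `fill`
.profile_matrix <- function(profile, fill = 0, significant_only = FALSE) {
  p <- tibble::as_tibble(profile)
  if (significant_only) p$rho[!p$significant] <- fill
  n_na <- sum(is.na(p$rho))
  if (n_na) rlang::inform(paste0("imputing ", n_na, " undefined correlation(s) as ", fill))
  p$rho[is.na(p$rho)] <- fill
  wide <- tidyr::pivot_wider(p[, c("entity", "parameter", "rho")],
                             names_from = "parameter", values_from = "rho")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$entity
  m
}

#' UPGMA clustering of correlation profiles
#'
#' Groups entities whose correlation signatures with the environmental
#' parameters are similar: average-linkage (UPGMA) agglomeration on
#' Euclidean distances between rows of the entity-by-parameter matrix of
#' Spearman coefficients. Undefined coefficients are imputed as 0.
#'
#' @param profile a `correlation_profile` (from [spearman_profile()]).
#' @param k optional number of flat clusters to cut.
#' @return an object of class `profile_clustering`: list with `hclust`, the
#'   profile `matrix`, and (when `k` is given) integer `clusters` named by
#'   entity.
#' @export
cluster_correlation_profiles <- function(profile, k = NULL) {
  m <- .profile_matrix(profile)
  if (nrow(m) == 1) {
    hc <- NULL
    clusters <- setNames(1L, rownames(m))
  } else {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
    clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  }
  structure(list(hclust = hc, matrix = m, clusters = clusters, k = k),
            class = "profile_clustering")
}

#' @method print profile_clustering
#' @export
print.profile_clustering <- function(x, ...) {
  cat("UPGMA clustering of", nrow(x$matrix), "correlation profiles over",
      ncol(x$matrix), "parameters\n")
  if (!is.null(x$clusters)) print(table(x$clusters))
  invisible(x)
}

#' @export
tidy.profile_clustering <- function(x, ...) {
  out <- tibble::tibble(entity = rownames(x$matrix))
  if (!is.null(x$clusters)) out$cluster <- unname(x$clusters[out$entity])
  out
}

#' @export
autoplot.profile_clustering <- function(object, ...) {
  ord <- if (!is.null(object$hclust)) object$hclust$order else seq_len(nrow(object$matrix))
  long <- tibble::as_tibble(object$matrix, rownames = "entity") |>
    tidyr::pivot_longer(-"entity", names_to = "parameter", values_to = "rho") |>
    dplyr::mutate(entity = factor(.data$entity, levels = rownames(object$matrix)[ord]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$entity,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r[S])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' PCA of significant correlation coefficients
#'
#' Sets non-significant cells of the entity-by-parameter Spearman matrix to
#' zero (encoding "no detected association"), column-centres the matrix, and
#' extracts principal components by singular value decomposition.
#'
#' @param profile a `correlation_profile`.
#' @param alpha significance threshold applied to the stored `significant`
#'   flag (cells failing it are zeroed).
#' @return object of class `correlation_pca`: list with `scores` (entities x
#'   components), `loadings` (parameters x components), `explained_variance`
#'   (fractions summing to 1 over the retained rank), and the zero-filled
#'   `matrix`. With an all-zero filtered matrix, zero scores and a warning
#'   are returned.
#' @export
pca_significant_correlations <- function(profile, alpha = 0.05) {
  m <- .profile_matrix(profile, significant_only = TRUE)
  if (nrow(m) < 2 || ncol(m) < 2) rlang::abort("need at least 2 entities and 2 parameters")
  if (all(m == 0)) {
    rlang::warn("no significant correlations; returning zero scores")
    return(structure(list(
      scores = matrix(0, nrow(m), 1, dimnames = list(rownames(m), "PC1")),
      loadings = matrix(0, ncol(m), 1, dimnames = list(colnames(m), "PC1")),
      explained_variance = 1, matrix = m
    ), class = "correlation_pca"))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-10
  if (!any(keep)) keep[1] <- TRUE
  ev <- pc$sdev[keep]^2 / sum(pc$sdev[keep]^2)
  structure(list(
    scores = pc$x[, keep, drop = FALSE],
    loadings = pc$rotation[, keep, drop = FALSE],
    explained_variance = ev,
    center = pc$center,
    matrix = m
  ), class = "correlation_pca")
}

#' @method print correlation_pca
#' @export
print.correlation_pca <- function(x, ...) {
  cat("PCA of significant correlations:", nrow(x$scores), "entities,",
      length(x$explained_variance), "components\n")
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.correlation_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "entity")
}

#' @export
glance.correlation_pca <- function(x, ...) {
  tibble::tibble(component = colnames(x$scores),
                 explained_variance = x$explained_variance)
}

#' @export
autoplot.correlation_pca <- function(object, ...) {
  sc <- tidy(object)
  if (ncol(sc) < 3) sc$PC2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = if (length(object$explained_variance) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]) else "PC2"
    ) +
    ggplot2::theme_minimal()
}
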