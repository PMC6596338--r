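#' Enrichment of taxa between habitat compartments
#'
#' For each taxon, divides its mean relative abundance across the target
#' compartment's samples by its mean across the source compartment's samples
#' (unweighted arithmetic means over samples, pooling sites and time points).
#' Taxa at or below detection in the source are censored: instead of an
#' infinite factor a lower bound `target_mean / detection_floor` is reported.
#'
#' @param rel_tbl relative-abundance tibble (`sample_id` + entity columns;
#'   entities may be OTUs or rank-aggregated taxa, typically from
#'   [merge_sample_fractions()] and [aggregate_taxa()]).
#' @param source_samples,target_samples character vectors of `sample_id`s
#'   forming the source and target compartments.
#' @param detection_floor divisor used for the censored lower bound when a
#'   taxon is undetected in the source; defaults to the smallest positive
#'   relative abundance observed among the source samples.
#' @return a tibble with columns `taxon`, `source_mean`, `target_mean`,
#'   `enrichment`, `lower_bound`, `flag` (`ok`, `absent_in_source`,
#'   `absent_in_both`).
#' @export
compartment_enrichment <- function(rel_tbl, source_samples, target_samples,
                                   detection_floor = NULL) {
  m <- otu_matrix(rel_tbl)
  miss <- setdiff(c(source_samples, target_samples), rownames(m))
  if (length(miss)) rlang::abort(paste0("samples not in table: ", paste(miss, collapse = ", ")))
  if (!length(source_samples) || !length(target_samples)) {
    rlang::abort("need at least one sample per compartment")
  }
  src <- m[source_samples, , drop = FALSE]
  tgt <- m[target_samples, , drop = FALSE]
  src_mean <- colMeans(src)
  tgt_mean <- colMeans(tgt)
  if (is.null(detection_floor)) {
    pos <- src[src > 0]
    detection_floor <- if (length(pos)) min(pos) else NA_real_
  }
  flag <- dplyr::case_when(
    src_mean == 0 & tgt_mean == 0 ~ "absent_in_both",
    src_mean == 0 ~ "absent_in_source",
    TRUE ~ "ok"
  )
  tibble::tibble(
    taxon = colnames(m),
    source_mean = src_mean,
    target_mean = tgt_mean,
    enrichment = ifelse(flag == "ok", tgt_mean / src_mean, NA_real_),
    lower_bound = ifelse(flag == "absent_in_source", tgt_mean / detection_floor, NA_real_),
    flag = flag
  )
}

#' OTUs shared between two compartments
#'
#' An OTU is "detected" in a compartment if it has at least one read in at
#' least one of that compartment's samples. The shared fraction is reported
#' relative to an explicit reference side:
#' `|detected(A) n detected(B)| / |detected(reference)|`.
#'
#' @param tbl count (or abundance) tibble containing both compartments'
#'   samples.
#' @param samples_a,samples_b sample ids of the two compartments.
#' @param reference which side the shared fraction is relative to
#'   (`"a"` or `"b"`).
#' @param restrict_to optional character vector of OTU ids (e.g. one phylum's
#'   OTUs) to which detection sets are restricted before comparison.
#' @return an object of class `shared_otu_report`: a list with `shared`
#'   (OTU ids), `detected_a`, `detected_b`, `fraction_shared`, `reference`.
#'   `tidy()` returns the per-OTU membership table.
#' @export
shared_otus <- function(tbl, samples_a, samples_b, reference = c("a", "b"),
                        restrict_to = NULL) {
  reference <- match.arg(reference)
  m <- otu_matrix(tbl)
  det <- function(ids) {
    sub <- m[ids, , drop = FALSE]
    colnames(sub)[colSums(sub > 0) > 0]
  }
  da <- det(samples_a); db <- det(samples_b)
  if (!is.null(restrict_to)) {
    da <- intersect(da, restrict_to)
    db <- intersect(db, restrict_to)
  }
  if (!length(da) || !length(db)) rlang::abort("empty detected OTU set in a compartment")
  sh <- intersect(da, db)
  ref_set <- if (reference == "a") da else db
  out <- list(
    shared = sh,
    detected_a = da,
    detected_b = db,
    fraction_shared = length(sh) / length(ref_set),
    reference = reference
  )
  class(out) <- "shared_otu_report"
  out
}

#' @method print shared_otu_report
#' @export
print.shared_otu_report <- function(x, ...) {
  cat("Shared-OTU report\n")
  cat("  detected in A:", length(x$detected_a), " in B:", length(x$detected_b), "\n")
  cat("  shared:", length(x$shared),
      sprintf(" (%.1f%% of reference '%s')\n", 100 * x$fraction_shared, x$reference))
  invisible(x)
}

#' @export
tidy.shared_otu_report <- function(x, ...) {
  ids <- union(x$detected_a, x$detected_b)
  tibble::tibble(
    otu_id = ids,
    detected_a = ids %in% x$detected_a,
    detected_b = ids %in% x$detected_b,
    shared = ids %in% x$shared
  )
}

#' Abundance contribution of a shared OTU set in a target community
#'
#' Sums the relative abundances of `shared` OTUs in each target sample.
#' With a `focal` OTU set (e.g. one phylum), the sum is renormalized within
#' the focal subset, answering "what part of the focal taxon's community is
#' made of shared (e.g. seepage-derived) OTUs"; without it, the raw sum
#' against the total community is returned.
#'
#' @param rel_tbl relative-abundance tibble for the target compartment.
#' @param shared character vector of shared OTU ids (from [shared_otus()]).
#' @param focal optional character vector of focal-taxon OTU ids.
#' @return tibble with `sample_id` and `contribution` in `[0, 1]` (`NA` where
#'   the focal taxon is absent from a sample).
#' @export
shared_abundance_contribution <- function(rel_tbl, shared, focal = NULL) {
  m <- otu_matrix(rel_tbl)
  if (is.null(focal)) {
    num <- rowSums(m[, intersect(colnames(m), shared), drop = FALSE])
    den <- rep(1, nrow(m))
  } else {
    foc <- intersect(colnames(m), focal)
    if (!length(foc)) rlang::abort("focal OTU set absent from table")
    num <- rowSums(m[, intersect(foc, shared), drop = FALSE])
    den <- rowSums(m[, foc, drop = FALSE])
  }
  tibble::tibble(
    sample_id = rownames(m),
    contribution = ifelse(den > 0, num / den, NA_real_)
  )
}

#' Taxonomic breakdown of a shared OTU set
#'
#' @param shared character vector of shared OTU ids.
#' @param taxonomy taxonomy tibble (`otu_id` + rank columns).
#' @param rank rank at which to summarise (default `"phylum"`).
#' @return tibble `taxon`, `n_otus`, `fraction`; fractions sum to 1. OTUs
#'   missing from the taxonomy are binned as `"unclassified"`.
#' @export
taxon_breakdown <- function(shared, taxonomy, rank = "phylum") {
  if (!length(shared)) rlang::abort("empty shared set")
  lin <- taxonomy[[rank]][match(shared, taxonomy$otu_id)]
  lin[is.na(lin)] <- "unclassified"
  tab <- sort(table(lin), decreasing = TRUE)
  tibble::tibble(
    taxon = names(tab),
    n_otus = as.integer(tab),
    fraction = as.integer(tab) / length(shared)
  )
}
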