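#' Rarefy an OTU table to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` total reads are dropped (and
#' reported); they are never padded. A fixed `seed` makes the draw
#' reproducible.
#'
#' @param tbl an OTU count tibble (`sample_id` + integer OTU columns).
#' @param depth target reads per sample (the study default for assembly
#'   analyses is 7876).
#' @param seed optional integer seed.
#' @return a rarefied OTU count tibble whose retained rows each sum to
#'   `depth`; dropped sample ids are attached as attribute
#'   `"dropped_samples"`. Zero-total OTU columns created by the subsampling
#'   are removed.
#' @export
rarefy <- function(tbl, depth, seed = NULL) {
  if (depth < 1) rlang::abort("depth must be >= 1")
  m <- otu_matrix(tbl)
  totals <- rowSums(m)
  keep <- totals >= depth
  if (!any(keep)) rlang::abort("no sample reaches the requested depth")
  dropped <- rownames(m)[!keep]
  if (length(dropped)) {
    rlang::inform(paste0("dropping ", length(dropped), " sample(s) below depth ",
                         depth, ": ", paste(dropped, collapse = ", ")))
  }
  m <- m[keep, , drop = FALSE]
  rar <- with_seed_opt(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    # vegan flags tables without singletons as possibly non-count data; our
    # inputs are validated integer counts, so the heuristic is noise here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  rar <- rar[, colSums(rar) > 0, drop = FALSE]
  out <- otu_tibble(rar)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Convert counts to relative abundances
#'
#' @param tbl an OTU count tibble; every sample total must be positive.
#' @return a tibble of the same shape whose rows each sum to 1.
#' @export
relative_abundance <- function(tbl) {
  m <- otu_matrix(tbl)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    rlang::abort(paste0("zero-total sample(s): ",
                        paste(rownames(m)[totals <= 0], collapse = ", ")))
  }
  otu_tibble(m / totals)
}
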