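#' qPCR-derived filter-fraction weights
#'
#' For every `(site, time_point)` with both a 0.1 um (`F01`) and a 0.2 um
#' (`F02`) qPCR measurement, computes the contribution of each filter
#' fraction to the total community:
#' `w_f = copies_f / (copies_F01 + copies_F02)`.
#' Pairs missing either fraction are flagged unusable rather than guessed.
#'
#' @param qpcr a tibble with columns `site`, `time_point`, `fraction`
#'   (`F01`/`F02`), `gene_copies_per_l` (see [read_qpcr()]).
#' @return a tibble with columns `site`, `time_point`, `w_f01`, `w_f02`,
#'   `usable`; for usable rows `w_f01 + w_f02 == 1`.
#' @export
fraction_weights <- function(qpcr) {
  wide <- qpcr |>
    dplyr::filter(.data$fraction %in% c("F01", "F02")) |>
    tidyr::pivot_wider(id_cols = c("site", "time_point"),
                       names_from = "fraction",
                       values_from = "gene_copies_per_l")
  for (f in c("F01", "F02")) if (!f %in% names(wide)) wide[[f]] <- NA_real_
  wide |>
    dplyr::mutate(
      usable = !is.na(.data$F01) & !is.na(.data$F02) &
        .data$F01 > 0 & .data$F02 > 0,
      w_f01 = ifelse(.data$usable, .data$F01 / (.data$F01 + .data$F02), NA_real_),
      w_f02 = ifelse(.data$usable, .data$F02 / (.data$F01 + .data$F02), NA_real_)
    ) |>
    dplyr::select("site", "time_point", "w_f01", "w_f02", "usable")
}

#' Merge two filter-fraction profiles into a whole-community profile
#'
#' The merged community is the convex combination
#' `w_f01 * rel_f01 + w_f02 * rel_f02` of the two fraction profiles, i.e. the
#' relative abundances of each fraction corrected by the fraction's qPCR
#' weight and summed. OTUs missing from one fraction are aligned by union
#' with zeros.
#'
#' @param rel_f01,rel_f02 named numeric vectors of relative abundances
#'   (each summing to 1) for the 0.1 um and 0.2 um fraction.
#' @param w_f01,w_f02 non-negative weights summing to 1.
#' @return a named numeric vector over the union of OTUs, summing to 1.
#' @export
merge_fractions <- function(rel_f01, rel_f02, w_f01, w_f02) {
  if (abs(w_f01 + w_f02 - 1) > 1e-12 || w_f01 < 0 || w_f02 < 0) {
    rlang::abort("fraction weights must be non-negative and sum to 1")
  }
  for (r in list(rel_f01, rel_f02)) {
    if (abs(sum(r) - 1) > 1e-9) rlang::abort("fraction profiles must each sum to 1")
  }
  al <- align_union(rel_f01, rel_f02)
  merged <- w_f01 * al$x + w_f02 * al$y
  merged
}

#' Merge all fractionated samples of an OTU table
#'
#' Groups water samples by `(site, time_point)`, converts each fraction to
#' relative abundances, looks up qPCR weights, and merges via
#' [merge_fractions()]. Bulk (unfractionated) samples are passed through as
#' relative abundances. A sample with only one usable fraction is passed
#' through as bulk with an informative message, never silently merged.
#'
#' @param tbl an OTU count tibble containing the fraction samples.
#' @param metadata sample metadata resolving each `sample_id` to
#'   `(compartment, site, time_point, fraction)`.
#' @param qpcr qPCR table used to compute weights (see [fraction_weights()]).
#' @return a tibble of merged relative abundances, one row per merged
#'   community with `sample_id = "<site>_<time_point>"`; rows sum to 1. The
#'   weights used are attached as attribute `"weights"` and a sample map as
#'   attribute `"sample_map"`.
#' @export
merge_sample_fractions <- function(tbl, metadata, qpcr) {
  m <- otu_matrix(tbl)
  md <- metadata[match(rownames(m), metadata$sample_id), ]
  if (anyNA(md$sample_id)) rlang::abort("OTU table contains samples absent from metadata")
  w <- fraction_weights(qpcr)
  rel <- m / rowSums(m)

  groups <- dplyr::distinct(md, .data$site, .data$time_point)
  rows <- list(); used_w <- list(); map <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- md$site == g$site & md$time_point == g$time_point
    fr <- md$fraction[sel]
    ids <- md$sample_id[sel]
    merged_id <- paste(g$site, g$time_point, sep = "_")
    if (all(fr == "bulk")) {
      for (k in which(sel)) {
        rows[[md$sample_id[k]]] <- rel[md$sample_id[k], ]
        map[[md$sample_id[k]]] <- tibble::tibble(sample_id = md$sample_id[k],
                                                 source = "bulk")
      }
      next
    }
    wi <- w[w$site == g$site & w$time_point == g$time_point, ]
    have_both <- all(c("F01", "F02") %in% fr) && nrow(wi) == 1 && isTRUE(wi$usable)
    if (have_both) {
      r01 <- rel[ids[fr == "F01"][1], ]
      r02 <- rel[ids[fr == "F02"][1], ]
      rows[[merged_id]] <- merge_fractions(r01, r02, wi$w_f01, wi$w_f02)
      used_w[[merged_id]] <- tibble::tibble(sample_id = merged_id, site = g$site,
                                            time_point = g$time_point,
                                            w_f01 = wi$w_f01, w_f02 = wi$w_f02)
      map[[merged_id]] <- tibble::tibble(sample_id = merged_id, source = "merged")
    } else {
      rlang::inform(paste0(merged_id, ": fraction pair incomplete or weights unusable; ",
                           "using available fraction(s) as bulk"))
      for (k in which(sel)) {
        rows[[md$sample_id[k]]] <- rel[md$sample_id[k], ]
        map[[md$sample_id[k]]] <- tibble::tibble(sample_id = md$sample_id[k],
                                                 source = "single_fraction_bulk")
      }
    }
  }
  out_m <- do.call(rbind, rows)
  out <- otu_tibble(out_m)
  attr(out, "weights") <- dplyr::bind_rows(used_w)
  attr(out, "sample_map") <- dplyr::bind_rows(map)
  out
}

#' Share of a taxon's population passing the 0.2 um filter
#'
#' Estimates, for a taxon observed in both filter fractions of one sample,
#' the share of its total population found in the ultra-small (0.1 um)
#' fraction: `w_f01 * rel_f01 / (w_f01 * rel_f01 + w_f02 * rel_f02)`.
#' Returns `NA` for taxa absent from both fractions.
#'
#' @param rel_f01,rel_f02 taxon relative abundances in each fraction
#'   (vectorized over taxa).
#' @param w_f01,w_f02 qPCR fraction weights summing to 1.
#' @return numeric vector of shares in `[0, 1]`.
#' @export
ultrasmall_share <- function(rel_f01, rel_f02, w_f01, w_f02) {
  num <- w_f01 * rel_f01
  den <- num + w_f02 * rel_f02
  ifelse(den > 0, num / den, NA_real_)
}

#' Fraction enrichment factor of a taxon
#'
#' Ratio of a taxon's relative abundance in the 0.1 um fraction to that in
#' the 0.2 um fraction. Values above 1 indicate enrichment among ultra-small
#' cells. Taxa absent from the 0.2 um reference fraction are flagged rather
#' than reported as infinite.
#'
#' @param rel_f01,rel_f02 taxon relative abundances in each fraction
#'   (vectorized; names are carried through).
#' @return a tibble with columns `taxon` (if names were given), `rel_f01`,
#'   `rel_f02`, `enrichment`, `flag` (`ok` / `absent_in_reference` /
#'   `absent_in_both`).
#' @export
fraction_enrichment <- function(rel_f01, rel_f02) {
  flag <- dplyr::case_when(
    rel_f01 == 0 & rel_f02 == 0 ~ "absent_in_both",
    rel_f02 == 0 ~ "absent_in_reference",
    TRUE ~ "ok"
  )
  out <- tibble::tibble(
    taxon = names(rel_f01) %||% as.character(seq_along(rel_f01)),
    rel_f01 = as.numeric(rel_f01),
    rel_f02 = as.numeric(rel_f02),
    enrichment = ifelse(flag == "ok", rel_f01 / rel_f02, NA_real_),
    flag = flag
  )
  out
}

#' Aggregate OTU-level profiles to a taxonomic rank
#'
#' Sums OTU columns sharing the same lineage value at `rank`. Because
#' fraction merging is linear, aggregating merged OTU profiles equals merging
#' rank-aggregated fraction profiles.
#'
#' @param tbl an abundance tibble (`sample_id` + OTU columns; counts or
#'   relative abundances).
#' @param taxonomy taxonomy tibble with `otu_id` and rank columns.
#' @param rank name of the rank column to aggregate at (e.g. `"phylum"`).
#' @return a tibble `sample_id` + one column per taxon at `rank`; OTUs
#'   lacking taxonomy are binned as `"unclassified"`.
#' @export
aggregate_taxa <- function(tbl, taxonomy, rank) {
  if (!rank %in% names(taxonomy)) rlang::abort(paste0("no rank column '", rank, "' in taxonomy"))
  m <- otu_matrix(tbl)
  lin <- taxonomy[[rank]][match(colnames(m), taxonomy$otu_id)]
  lin[is.na(lin)] <- "unclassified"
  agg <- t(rowsum(t(m), group = lin))
  otu_tibble(agg)
}
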