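#' Read an OTU count table
#'
#' Reads a tab-separated samples-by-OTUs count table. Two dialects are
#' supported: `"tsv"` (first column holds sample identifiers, header row holds
#' OTU identifiers) and `"mothur"` (a mothur "shared" file whose three leading
#' columns `label`, `Group`, `numOtus` are dropped, `Group` becoming the
#' sample identifier). With `dialect = "auto"` the mothur dialect is detected
#' from those leading column names.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @param dialect one of `"auto"`, `"tsv"`, `"mothur"`.
#' @return a validated tibble: `sample_id` column plus one integer column per
#'   OTU (see [validate_otu_table()]).
#' @seealso [write_otu_table()], [rarefy()], [relative_abundance()]
#' @export
read_otu_table <- function(path, dialect = c("auto", "tsv", "mothur")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         name_repair = "minimal")
  lead <- tolower(names(tbl)[seq_len(min(3L, ncol(tbl)))])
  is_shared <- length(lead) == 3 && identical(lead, c("label", "group", "numotus"))
  if (dialect == "auto") dialect <- if (is_shared) "mothur" else "tsv"
  if (dialect == "mothur") {
    if (!is_shared) rlang::abort("not a mothur shared file: expected leading columns label/Group/numOtus")
    tbl <- tbl[, -c(1L, 3L)]
    names(tbl)[1] <- "sample_id"
  } else {
    names(tbl)[1] <- "sample_id"
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_otu_table(tbl)
}

#' Write an OTU count table as plain TSV
#'
#' @param tbl an OTU count tibble (`sample_id` + OTU columns).
#' @param path destination path.
#' @return `tbl`, invisibly.
#' @export
write_otu_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Validate an OTU count table
#'
#' Checks that sample and OTU identifiers are unique, that all counts are
#' non-negative integers, and drops OTU columns whose total count is zero
#' (these may arise transiently from subsetting but are not allowed in a
#' validated table).
#'
#' @param tbl a data frame: first column sample identifiers, remaining columns
#'   numeric counts.
#' @return the validated tibble (zero-total OTUs removed).
#' @export
validate_otu_table <- function(tbl) {
  m <- otu_matrix(tbl)
  if (anyDuplicated(rownames(m))) {
    rlang::abort("duplicate sample identifiers in OTU table")
  }
  if (anyDuplicated(colnames(m))) {
    rlang::abort("duplicate OTU identifiers in OTU table")
  }
  if (anyNA(m)) rlang::abort("missing values in OTU counts")
  if (any(m < 0)) rlang::abort("negative values in OTU counts")
  if (max(abs(m - round(m))) > 1e-8) rlang::abort("non-integer values in OTU counts")
  empty <- colSums(m) == 0
  if (any(empty)) {
    rlang::inform(paste0("dropping ", sum(empty), " OTU(s) with zero total count"))
    m <- m[, !empty, drop = FALSE]
  }
  out <- otu_tibble(round(m))
  names(out)[1] <- "sample_id"
  out
}

#' Read a sample metadata table
#'
#' CSV with required columns `sample_id`, `compartment` (soil / seepage /
#' groundwater), `site`, `time_point`, `fraction` (`F01` = 0.1 um filter,
#' `F02` = 0.2 um filter, `bulk` = unfractionated) and `assemblage` (`HTL`,
#' `HTU` or `none`).
#'
#' @param path path to a CSV file.
#' @return a validated tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a data frame to validate in place of a file.
#' @export
validate_sample_metadata <- function(metadata) {
  req <- c("sample_id", "compartment", "site", "time_point", "fraction", "assemblage")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols)) {
    rlang::abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) rlang::abort("duplicate sample_id in metadata")
  bad_comp <- setdiff(unique(metadata$compartment), c("soil", "seepage", "groundwater"))
  if (length(bad_comp)) rlang::abort(paste0("unknown compartment: ", paste(bad_comp, collapse = ", ")))
  bad_frac <- setdiff(unique(metadata$fraction), c("F01", "F02", "bulk"))
  if (length(bad_frac)) rlang::abort(paste0("unknown fraction: ", paste(bad_frac, collapse = ", ")))
  soil_frac <- metadata$fraction[metadata$compartment == "soil"]
  if (any(soil_frac != "bulk")) rlang::abort("soil samples must have fraction = bulk")
  tibble::as_tibble(metadata)
}

#' Read a qPCR table of 16S rRNA gene copy numbers
#'
#' CSV with columns `site`, `time_point`, `fraction` and `gene_copies_per_l`
#' (16S rRNA gene copies per litre, positive).
#'
#' @param path path to a CSV file.
#' @return a tibble.
#' @export
read_qpcr <- function(path) {
  q <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), time_point = readr::col_character(),
    fraction = readr::col_character(), gene_copies_per_l = readr::col_double()
  ), progress = FALSE)
  if (any(!is.na(q$gene_copies_per_l) & q$gene_copies_per_l <= 0)) {
    rlang::abort("gene_copies_per_l must be positive")
  }
  q
}

#' Read a hydrochemistry table
#'
#' CSV with columns `site`, `time_point` and one numeric column per measured
#' parameter (dissolved oxygen, nitrate, ...). Missing values are allowed and
#' must be encoded as empty cells or `NA`.
#'
#' @param path path to a CSV file.
#' @return a tibble with a derived `sample_id` column (`site` and `time_point`
#'   joined by `_`) for alignment with merged community profiles.
#' @export
read_hydrochem <- function(path) {
  h <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), time_point = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(names(h))) rlang::abort("duplicate parameter names in hydrochemistry table")
  dplyr::mutate(h, sample_id = paste(.data$site, .data$time_point, sep = "_"),
                .before = 1)
}

#' Read an OTU taxonomy table
#'
#' Tab-separated, column `otu_id` plus one column per rank
#' (`domain` ... `genus`); lower ranks may be `"unclassified"`.
#'
#' @param path path to a TSV file.
#' @return a tibble.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"otu_id" %in% names(tx)) rlang::abort("taxonomy table lacks an otu_id column")
  if (anyDuplicated(tx$otu_id)) rlang::abort("duplicate otu_id in taxonomy table")
  tx
}

#' Cross-validate a set of related inputs
#'
#' Checks that every sample in the OTU table resolves to exactly one metadata
#' row, that the tree's tip set covers the table's OTUs, and that the taxonomy
#' covers the table's OTUs.
#'
#' @param otu_table an OTU count tibble.
#' @param metadata a sample metadata tibble (optional).
#' @param tree a rooted `phylo` tree with OTU tip labels (optional).
#' @param taxonomy a taxonomy tibble (optional).
#' @return `TRUE`, invisibly; errors describe any unresolved references.
#' @export
validate_bundle <- function(otu_table, metadata = NULL, tree = NULL, taxonomy = NULL) {
  otus <- setdiff(names(otu_table), "sample_id")
  if (!is.null(metadata)) {
    missing_md <- setdiff(otu_table$sample_id, metadata$sample_id)
    if (length(missing_md)) {
      rlang::abort(paste0("samples without metadata: ", paste(head(missing_md, 5), collapse = ", ")))
    }
  }
  if (!is.null(tree)) {
    missing_tip <- setdiff(otus, tree$tip.label)
    if (length(missing_tip)) {
      rlang::abort(paste0("OTUs absent from tree: ", paste(head(missing_tip, 5), collapse = ", ")))
    }
  }
  if (!is.null(taxonomy)) {
    missing_tax <- setdiff(otus, taxonomy$otu_id)
    if (length(missing_tax)) {
      rlang::abort(paste0("OTUs without taxonomy: ", paste(head(missing_tax, 5), collapse = ", ")))
    }
  }
  invisible(TRUE)
}
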