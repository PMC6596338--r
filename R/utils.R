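# internal helpers shared across modules

# Convert a wide OTU tibble (first column = sample identifier, remaining
# columns = per-OTU numeric values) into a numeric matrix with sample row
# names. The inverse of `otu_tibble()`.
otu_matrix <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    rlang::abort("expected a data frame with a sample-id column plus >=1 OTU column")
  }
  df <- as.data.frame(tbl)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) rlang::abort("OTU columns must all be numeric")
  rownames(m) <- as.character(df[[1]])
  m
}

otu_tibble <- function(m, id_col = "sample_id") {
  out <- tibble::as_tibble(m, rownames = id_col, .name_repair = "minimal")
  names(out)[1] <- id_col
  out
}

# run `expr` under a temporary RNG state seeded with `seed`; a NULL seed
# leaves the ambient RNG stream untouched
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible 32-bit substream seed from a run seed
substream_seed <- function(seed, index) {
  (as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647
}

# align two named numeric vectors on the union of their names, filling zeros
align_union <- function(x, y) {
  nms <- union(names(x), names(y))
  xx <- setNames(numeric(length(nms)), nms)
  yy <- xx
  xx[names(x)] <- x
  yy[names(y)] <- y
  list(x = xx, y = yy, names = nms)
}

`%||%` <- rlang::`%||%`
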