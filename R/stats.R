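# rank statistics with exact small-sample p-values
# (implemented in-package because the stats:: versions cannot produce exact
#  p-values in the presence of midrank ties)

# all permutations of 1..n as an (n! x n) matrix, rows in a deterministic order
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(rep.int(i, nrow(p)), q)
  }))
}

.spearman_rho <- function(rx, ry) {
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cov(rx, ry) / (sx * sy)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Midrank ties; the coefficient is the Pearson correlation of the midranks.
#' For `n <= exact_max` (default 9) the two-sided p-value is computed by
#' exact enumeration of all `n!` rank permutations; otherwise via the t
#' approximation `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @param exact_max largest n for which the permutation-exact p is used.
#' @return list with `rho`, `p_value`, `n`, `method`; `rho` is `NA` (with
#'   `method = "undefined"`) when either vector is constant.
#' @export
spearman_test <- function(x, y, exact_max = 9) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- .spearman_rho(rx, ry)
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  if (n <= exact_max) {
    perms <- .permutations(n)
    # rho for every permutation of ry, vectorized over rows
    ry_perm <- matrix(ry[t(perms)], nrow = n)
    rho_all <- as.numeric(stats::cor(rx, ry_perm))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Mann-Whitney U test with exact tie-aware p-value
#'
#' `U` is computed for the first group from midranks:
#' `U = R1 - n1*(n1+1)/2`. For combined sample sizes up to `exact_max`
#' (default 20) the two-sided p-value is exact, enumerating all
#' `choose(n1+n2, n1)` group assignments of the observed (possibly tied)
#' values; beyond that a normal approximation with tie-corrected variance is
#' used. Rank-based, hence invariant under monotone transforms of the data.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max largest combined n for which the exact p is used.
#' @return list with `u`, `p_value`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) rlang::abort("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * (nn + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  list(u = u, p_value = p, n_x = n1, n_y = n2, method = method)
}
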