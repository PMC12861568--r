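# Statistical comparison of per-structure density distributions:
# Mann-Whitney U (exact by enumeration for small samples, tie- and
# continuity-corrected normal approximation otherwise) with Bonferroni
# adjustment over the pairwise comparisons, as used for the electron
# density panels.

#' Mann-Whitney U test
#'
#' U is computed from midranks (tie-corrected). For `n1 + n2 <= 16` the
#' two-sided p-value is exact: the permutation distribution of U is fully
#' enumerated over all `choose(n1 + n2, n1)` group assignments of the
#' observed midranks, and the smaller tail (including the observed value)
#' is doubled, capped at 1. For larger samples the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return object of class `mw_test`: list with `U` (statistic for the
#'   first sample), `p.value`, `method` (`"exact"` or `"normal_approx"`),
#'   `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= 16) {
    Us <- enumerate_u(r, n1)
    eps <- 1e-9
    p_lo <- mean(Us <= U + eps)
    p_hi <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    # double arithmetic: n1 * n2 overflows integers for voxel-scale samples
    n1d <- as.numeric(n1); n2d <- as.numeric(n2); Nd <- as.numeric(N)
    mu <- n1d * n2d / 2
    ties <- rle(sort(r))$lengths
    tie_term <- sum(as.numeric(ties)^3 - ties) / (Nd * (Nd - 1))
    sigma2 <- n1d * n2d / 12 * ((Nd + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p.value = p, method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

# all U values over the permutation distribution of the observed midranks;
# the index combinations are cached per (N, n1)
enumerate_u <- function(r, n1) {
  N <- length(r)
  key <- paste0("C", N, "_", n1)
  combos <- .xpct_cache[[key]]
  if (is.null(combos)) {
    combos <- utils::combn(N, n1)
    .xpct_cache[[key]] <- combos
  }
  colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = %d + %d, p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p.value))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p, with `m` the number of tests actually
#' performed (defaults to `length(pvals)`).
#'
#' @param pvals p-values in \[0, 1\].
#' @param m number of comparisons.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "bonferroni", n = max(m, length(pvals)))
}

#' Per-class density report with pairwise tests
#'
#' Summarizes the density distribution of each class and runs all pairwise
#' Mann-Whitney U tests with Bonferroni correction over the performed
#' pairs (the Figure-style box-plot readout). Classes with fewer than
#' `min_n` observations are flagged and excluded from testing.
#'
#' @param values named list of numeric vectors: per-class density samples
#'   (e.g. relative electron densities of individual ROIs or voxels).
#' @param min_n minimum group size for testing.
#' @param plot produce a ggplot2 box plot alongside the table.
#' @return list of class `density_report`: `report` (data frame with one
#'   row per class and one per tested pair), `tests`, `excluded`, `plot`.
#' @export
density_report <- function(values, min_n = 3L, plot = TRUE) {
  stopifnot(is.list(values), length(values) >= 2,
            !is.null(names(values)))
  cls_rows <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(row_type = "class", group1 = nm, group2 = NA,
               n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3], U = NA, p = NA, p_adj = NA,
               stringsAsFactors = FALSE)
  }))
  small <- names(values)[vapply(values, length, 1L) < min_n]
  testable <- setdiff(names(values), small)
  pairs <- if (length(testable) >= 2) utils::combn(testable, 2) else
    matrix(character(0), 2, 0)
  tests <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tt <- mann_whitney_u(values[[a]], values[[b]])
    data.frame(row_type = "test", group1 = a, group2 = b,
               n = tt$n1 + tt$n2, mean = NA, median = NA, q1 = NA, q3 = NA,
               U = tt$U, p = tt$p.value, p_adj = NA,
               stringsAsFactors = FALSE)
  })
  test_rows <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(test_rows))
    test_rows$p_adj <- bonferroni_adjust(test_rows$p)
  report <- rbind(cls_rows, test_rows)
  pl <- NULL
  if (plot) {
    df <- data.frame(
      class = rep(names(values), vapply(values, length, 1L)),
      value = unlist(values, use.names = FALSE))
    pl <- ggplot2::ggplot(df, ggplot2::aes(x = class, y = value)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::labs(x = NULL,
                    y = expression(paste(Delta, rho[e], " (e/nm"^3, ")"))) +
      ggplot2::theme_minimal()
  }
  structure(list(report = report, tests = test_rows, excluded = small,
                 plot = pl),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  print(x$report, digits = 4)
  if (length(x$excluded))
    cat("excluded from testing (n too small):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
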