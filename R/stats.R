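#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 1, finite.
#' @return list with `mean`, `sem` (sample SD over `sqrt(n)`; `NA` for
#'   `n = 1`) and `n`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Two-sided unpaired Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups, as used for per-brain
#' laterality metrics. The U statistic is computed from mid-ranks. With no
#' ties and a pooled size of at most 20, the two-sided p-value is exact:
#' all `choose(n1 + n2, n1)` assignments of the pooled values to groups are
#' enumerated and the smaller tail probability is doubled (capped at 1) —
#' the convention of common ranked-test software. With ties or larger
#' samples, a normal approximation with tie and continuity corrections is
#' used and flagged in `method`.
#'
#' @param x,y numeric vectors, both non-empty, all values finite.
#' @return an object of class `group_comparison`: `U` (for the first
#'   group), `p`, `method` (`"exact"` or `"normal-approx-tied"`), `n1`,
#'   `n2`, and per-group summaries `group1`/`group2` from [mean_sem()].
#' @export
mann_whitney_two_sided <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("values must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && N <= 20L) {
    # Exact null: every assignment of ranks 1..N to group 1 is equally
    # likely; with no ties the pooled ranks are exactly 1..N.
    assign_mat <- utils::combn(N, n1)
    rank_sums <- colSums(matrix(seq_len(N)[assign_mat], nrow = n1))
    U_all <- rank_sums - n1 * (n1 + 1) / 2
    lower <- mean(U_all <= U)
    upper <- mean(U_all >= U)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # All values identical: no evidence either way.
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approx-tied"
  }
  structure(
    list(U = U, p = p, method = method, n1 = n1, n2 = n2,
         group1 = mean_sem(x), group2 = mean_sem(y)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Mann-Whitney U = %g, two-sided p = %.4g (%s)\n",
              x$U, x$p, x$method))
  cat(sprintf("  group 1 (n=%d): mean %.4g +/- %.4g SEM\n",
              x$group1$n, x$group1$mean, x$group1$sem))
  cat(sprintf("  group 2 (n=%d): mean %.4g +/- %.4g SEM\n",
              x$group2$n, x$group2$mean, x$group2$sem))
  invisible(x)
}
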