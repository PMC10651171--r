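#' @include utils.R
NULL

#' Within-group median-versus-zero test of combined effects
#'
#' Wilcoxon signed-rank test against zero on per-subject combined clustered
#' effects (normal approximation, zeros dropped, midrank ties), with the Z
#' sign matching the direction of the rank sum. A pure sign-test mode is
#' available.
#'
#' @param values per-subject combined effects (n >= 5, not all zero).
#' @param mode "signed_rank" (default) or "sign" (binomial sign test).
#' @return list (test, Z, p, n) of class "herclust_stat".
#' @export
medianVsZeroTest <- function(values, mode = c("signed_rank", "sign")) {
  mode <- match.arg(mode)
  if (length(values) < 5) stop("medianVsZeroTest: need at least 5 subjects")
  if (all(values == 0)) stop("medianVsZeroTest: all values zero (degenerate)")
  if (mode == "signed_rank") {
    r <- signedRankZ(values)
    out <- list(test = "SIGNED_RANK", Z = r$Z, p = r$p, n = r$n)
  } else {
    v <- values[values != 0]
    k <- sum(v > 0); n <- length(v)
    p <- min(1, 2 * stats::pbinom(min(k, n - k), n, 0.5))
    Z <- (k - n / 2) / sqrt(n / 4)
    out <- list(test = "SIGN", Z = Z, p = p, n = n)
  }
  class(out) <- "herclust_stat"
  out
}

#' Spearman rank correlation between two per-subject measures
#'
#' Midrank-based Spearman R with a two-sided p from the t approximation.
#'
#' @param x,y equal-length numeric vectors (n >= 5).
#' @return list (test, R, p, n) of class "herclust_stat".
#' @export
spearmanAssoc <- function(x, y) {
  if (length(x) != length(y)) stop("spearmanAssoc: unequal lengths")
  n <- length(x)
  if (n < 5) stop("spearmanAssoc: need at least 5 subjects")
  if (sd(x) == 0 || sd(y) == 0) stop("spearmanAssoc: constant input (degenerate)")
  R <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  tStat <- R * sqrt((n - 2) / (1 - R^2 + 1e-300))
  p <- if (abs(R) >= 1) 0 else 2 * pt(-abs(tStat), n - 2)
  out <- list(test = "SPEARMAN", R = R, p = p, n = n)
  class(out) <- "herclust_stat"
  out
}

#' Bonferroni annotation of a result family
#'
#' Flags each result significant when its p is below alpha / m; the family
#' size defaults to the 8 tests of the two-group x two-signal x two-level
#' design.
#'
#' @param family list of results (each with a \code{p}), or a data.frame with
#'   a \code{p} column.
#' @param m family size (default 8).
#' @param alpha base level (default 0.05).
#' @return the family with \code{alpha_corrected} and \code{significant}
#'   added.
#' @export
bonferroniAdjust <- function(family, m = 8, alpha = 0.05) {
  if (m < 1) stop("bonferroniAdjust: m must be >= 1")
  thr <- alpha / m
  if (is.data.frame(family)) {
    family$alpha_corrected <- thr
    family$significant <- family$p < thr
    return(family)
  }
  lapply(family, function(r) {
    r$alpha_corrected <- thr
    r$significant <- r$p < thr
    r
  })
}

#' @export
print.herclust_stat <- function(x, ...) {
  if (!is.null(x$Z)) cat(sprintf("%s: Z = %.4f, p = %.4g, n = %d\n", x$test, x$Z, x$p, x$n))
  else cat(sprintf("%s: R = %.4f, p = %.4g, n = %d\n", x$test, x$R, x$p, x$n))
  invisible(x)
}
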