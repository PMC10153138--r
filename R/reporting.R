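#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum comparison used for all group contrasts. For combined n <= 20
#' with no ties the exact U distribution is used; otherwise the normal
#' approximation with continuity and tie correction. The method actually
#' used is recorded in the result.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param alternative \code{"two_sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @param group_names labels for the two groups.
#' @return object of class \code{comparison_result}: \code{group_names},
#'   \code{n}, \code{u_statistic} (U of the first group), \code{p_value},
#'   \code{medians}, \code{method}, \code{alternative}.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "less", "greater"),
                         group_names = c("x", "y")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("groups must be finite")
  alt <- sub("two_sided", "two.sided", alternative, fixed = TRUE)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE))
  structure(list(group_names = group_names,
                 n = c(length(x), length(y)),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 medians = c(median(x), median(y)),
                 method = if (exact) "exact"
                          else "normal approximation (tie/continuity corrected)",
                 alternative = alternative),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<mann_whitney> %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$group_names[1], x$n[1], x$medians[1],
              x$group_names[2], x$n[2], x$medians[2]))
  cat(sprintf("  U = %g, p = %.4g (%s, %s)\n",
              x$u_statistic, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Aggregate per-object measurements to per-embryo means
#'
#' The embryo, not the cap/spindle/nucleus, is the unit of analysis: group
#' comparisons operate on one mean value per embryo.
#'
#' @param rows data frame of per-object measurements.
#' @param value_col name of the measurement column.
#' @param id_col name of the embryo id column (default \code{"embryo"}).
#' @return data frame with one row per embryo: id column, \code{n},
#'   \code{mean_value}.
#' @export
aggregate_per_embryo <- function(rows, value_col, id_col = "embryo") {
  if (!value_col %in% names(rows)) stop("missing value column: ", value_col)
  if (!id_col %in% names(rows)) stop("missing embryo id column: ", id_col)
  ids <- rows[[id_col]]
  if (any(is.na(ids))) stop("rows with missing embryo ids")
  sp <- split(rows[[value_col]], ids)
  out <- data.frame(id = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean_value = vapply(sp, mean, numeric(1)))
  names(out)[1] <- id_col
  rownames(out) <- NULL
  out
}
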