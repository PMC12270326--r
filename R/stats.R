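# Nonparametric test wrappers used by the cohort comparison. The tests
# themselves are delegated to stats:: (Kruskal-Wallis with tie correction,
# Mann-Whitney U via the normal approximation with tie correction, Pearson
# chi-square with adjusted standardized residuals); the wrappers add the
# degenerate-input conventions the pipeline relies on.

#' Kruskal-Wallis rank test across groups
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups).
#' @return List with \code{H} (tie-corrected statistic), \code{df} and
#'   \code{p} (chi-square approximation). All-identical values yield
#'   \code{H = 0, p = 1}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(!vapply(groups, length, integer(1))))
    stop("kruskal_wallis: need >= 2 nonempty groups", call. = FALSE)
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney U test (two-sided, normal approximation)
#'
#' @param a,b Numeric vectors.
#' @return List with \code{U} (number of (a, b) pairs with a > b, ties
#'   counting one half) and two-sided \code{p} from the tie-corrected
#'   normal approximation without continuity correction. Identical
#'   samples yield \code{p = 1}.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    stop("mann_whitney: both samples must be nonempty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  U <- unname(wt$statistic)
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # zero rank variance: indistinguishable samples
  list(U = U, p = p)
}

#' Pearson chi-square homogeneity test with adjusted residuals
#'
#' @param table Matrix of nonnegative counts, at least 2 x 2, with no
#'   zero row or column margin.
#' @return List with \code{chi2}, \code{df}, \code{p}, \code{expected},
#'   \code{adjusted_residuals} (the standardized residuals
#'   \eqn{(O-E)/\sqrt{E(1-p_{row})(1-p_{col})}}) and \code{flagged}
#'   (|residual| > 1.96).
#' @export
chisq_homogeneity <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("chisq_homogeneity: need at least a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("chisq_homogeneity: counts must be nonnegative integers",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chisq_homogeneity: zero marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  res <- ct$stdres
  res[!is.finite(res)] <- 0
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = if (is.nan(ct$p.value)) 1 else ct$p.value,
       expected = ct$expected,
       adjusted_residuals = res,
       flagged = abs(res) > 1.96)
}

#' Two-test normality gate
#'
#' Reports a sample as normally distributed only when both the one-sample
#' Kolmogorov-Smirnov test against the fitted normal and its Lilliefors
#' correction give p > 0.05; the cohort summaries then use mean (sd),
#' otherwise median (IQR).
#'
#' @param x Numeric vector (n >= 4 for the Lilliefors test).
#' @param alpha Gate level.
#' @return List with \code{ks_p}, \code{lillie_p}, \code{normal}.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || stats::sd(x) == 0)
    return(list(ks_p = NA_real_, lillie_p = NA_real_, normal = FALSE))
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$p.value
  ll <- tryCatch(nortest::lillie.test(x)$p.value,
                 error = function(e) NA_real_)
  list(ks_p = ks, lillie_p = ll,
       normal = isTRUE(ks > alpha) && isTRUE(ll > alpha))
}

#' Compact letter display for pairwise contrasts
#'
#' After a significant omnibus test, assigns one letter (k, l, m, ...) to
#' each significant pairwise contrast, attached to both members of the
#' pair -- the annotation style of the cohort tables.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group names
#'   on the dimnames.
#' @param alpha Significance level.
#' @return Data frame of significant contrasts (\code{group1},
#'   \code{group2}, \code{p}, \code{letter}); zero rows when nothing is
#'   significant.
#' @export
letter_display <- function(p_matrix, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  nm <- rownames(p_matrix)
  out <- data.frame(group1 = character(0), group2 = character(0),
                    p = numeric(0), letter = character(0),
                    stringsAsFactors = FALSE)
  pool <- c("k", "l", "m", letters[14:26])
  li <- 0L
  for (i in seq_len(nrow(p_matrix) - 1L)) {
    for (j in (i + 1L):ncol(p_matrix)) {
      p <- p_matrix[i, j]
      if (is.finite(p) && p < alpha) {
        li <- li + 1L
        out[nrow(out) + 1L, ] <- list(nm[i], nm[j], p,
                                      pool[min(li, length(pool))])
      }
    }
  }
  out
}
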