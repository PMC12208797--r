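# Normality gate used throughout: Shapiro-Wilk at alpha = 0.05 per sample,
# matching the study-level significance convention. Returns NA for samples
# where the test is undefined (constant data, n outside 3..5000).
shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) return(NA_real_)
  if (stats::sd(x) == 0) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

comparison_row <- function(variable, groups, test, p, normality_p,
                           flags = character(0)) {
  structure(list(variable = variable, groups = groups, test = test,
                 p_value = p, normality_p = normality_p, flags = flags),
            class = "comparison_row")
}

#' @export
print.comparison_row <- function(x, ...) {
  g <- x$groups
  desc <- paste(vapply(seq_along(g), function(i)
    sprintf("%s: n=%d, %.3g +/- %.3g", names(g)[i] %||% paste0("g", i),
            g[[i]]$n, g[[i]]$mean, g[[i]]$sd), character(1)),
    collapse = " | ")
  cat(sprintf("<comparison> %s  [%s]\n  %s\n  p = %.4g%s\n",
              x$variable, x$test, desc, x$p_value,
              if (length(x$flags)) paste0("  (", paste(x$flags, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @export
as.data.frame.comparison_row <- function(x, ...) {
  g <- x$groups
  data.frame(
    variable = x$variable,
    n1 = g[[1]]$n, mean1 = g[[1]]$mean, sd1 = g[[1]]$sd,
    n2 = if (length(g) > 1) g[[2]]$n else NA_integer_,
    mean2 = if (length(g) > 1) g[[2]]$mean else NA_real_,
    sd2 = if (length(g) > 1) g[[2]]$sd else NA_real_,
    test = x$test, p_value = x$p_value,
    normality_p1 = x$normality_p[1],
    normality_p2 = if (length(x$normality_p) > 1) x$normality_p[2] else NA_real_,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

grp_desc <- function(x) list(n = length(x), mean = mean(x), sd = stats::sd(x))

#' Compare two independent samples with normality-gated test selection
#'
#' Shapiro-Wilk normality is assessed per sample; when both samples are
#' compatible with normality (p >= 0.05) the Student's (equal-variance)
#' t-test is used, otherwise the Mann-Whitney U test. Two-sided throughout.
#'
#' @param x,y numeric samples, each of length >= 3.
#' @param variable label carried into the result.
#' @param welch use Welch's t-test instead of Student's on the normal path.
#' @return A \code{comparison_row} with the test used, the p-value and the
#'   per-group normality p-values.
#' @export
compare_independent <- function(x, y, variable = "x vs y", welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop_corowia("corowia_insufficient_n",
                 sprintf("need n >= 3 per group (got %d, %d)",
                         length(x), length(y)))
  np <- c(shapiro_p(x), shapiro_p(y))
  flags <- character(0)
  if (stats::sd(c(x, y)) == 0) {
    return(comparison_row(variable, list(x = grp_desc(x), y = grp_desc(y)),
                          "student_t", 1, np, "degenerate_variance"))
  }
  if (all(!is.na(np)) && all(np >= 0.05)) {
    test <- if (welch) "welch_t" else "student_t"
    p <- stats::t.test(x, y, var.equal = !welch)$p.value
  } else {
    test <- "mann_whitney"
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  comparison_row(variable, list(x = grp_desc(x), y = grp_desc(y)),
                 test, p, np, flags)
}

#' Compare paired measurements with normality-gated test selection
#'
#' Normality of the paired differences gates the choice between the paired
#' Student's t-test and the Wilcoxon signed-rank test; two-sided. Degenerate
#' difference distributions (zero variance) are reported with an explicit
#' flag: identical samples give p = 1, an exact constant shift gives p = 0.
#'
#' @param pre,post paired numeric samples of equal length >= 3.
#' @param variable label carried into the result.
#' @return A \code{comparison_row}.
#' @export
compare_paired <- function(pre, post, variable = "pre vs post") {
  if (length(pre) != length(post))
    stop_corowia("corowia_pairing_error",
                 sprintf("sample lengths differ (%d vs %d)",
                         length(pre), length(post)))
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  if (length(pre) < 3L)
    stop_corowia("corowia_insufficient_n", "need n >= 3 complete pairs")
  d <- post - pre
  np <- shapiro_p(d)
  groups <- list(pre = grp_desc(pre), post = grp_desc(post))
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(comparison_row(variable, groups, "paired_t", p, np,
                          "degenerate_variance"))
  }
  if (!is.na(np) && np >= 0.05) {
    test <- "paired_t"
    p <- stats::t.test(post, pre, paired = TRUE)$p.value
  } else {
    test <- "wilcoxon"
    p <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)$p.value)
  }
  comparison_row(variable, groups, test, p, np)
}

#' Compare a 2x2 contingency table
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the chi-square test (without continuity correction).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param variable label carried into the result.
#' @return A \code{comparison_row}; group descriptors hold counts and
#'   proportions of the first column.
#' @export
compare_categorical <- function(tab, variable = "2x2 table") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop_corowia("corowia_parameter_error",
                 "tab must be a 2x2 matrix of non-negative integer counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop_corowia("corowia_degenerate_margin",
                 "empty row or column margin; association undefined")
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected < 5)) {
    test <- "fisher"
    p <- stats::fisher.test(tab)$p.value
  } else {
    test <- "chi_square"
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  }
  groups <- list(
    row1 = list(n = rs[[1]], mean = tab[1, 1] / rs[[1]], sd = NA_real_),
    row2 = list(n = rs[[2]], mean = tab[2, 1] / rs[[2]], sd = NA_real_)
  )
  comparison_row(variable, groups, test, p, c(NA_real_, NA_real_))
}

#' Correlation with normality-gated method selection
#'
#' Pearson's correlation when both samples pass the Shapiro-Wilk gate,
#' Spearman's rank correlation otherwise; the method can be forced.
#'
#' @param x,y numeric samples of equal length >= 3.
#' @param force_method optional \code{"pearson"} or \code{"spearman"}.
#' @return List with \code{coefficient}, \code{p}, \code{method} and the
#'   per-sample \code{normality_p}.
#' @export
correlate <- function(x, y, force_method = NULL) {
  if (length(x) != length(y))
    stop_corowia("corowia_pairing_error", "x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop_corowia("corowia_insufficient_n", "need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_corowia("corowia_degenerate_variance",
                 "zero variance in a sample; correlation undefined")
  np <- c(shapiro_p(x), shapiro_p(y))
  method <- if (!is.null(force_method))
    match.arg(force_method, c("pearson", "spearman"))
  else if (all(!is.na(np)) && all(np >= 0.05)) "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method,
                    exact = if (method == "spearman") FALSE else NULL))
  list(coefficient = unname(ct$estimate), p = ct$p.value,
       method = method, normality_p = np)
}
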