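# Group-level statistics: MANOVA on PCA-reduced spectra, t-tests from
# published summary statistics, and Pearson chi-squared tests of
# independence on contingency tables.

#' MANOVA on PCA-reduced spectra
#'
#' Used to validate the spectral consistency of two control sub-groups
#' (e.g. PCOS vs healthy) before pooling them: PCA is fitted on the pooled
#' rows retaining `variance_target` cumulative variance, and a one-way
#' MANOVA (Wilks' lambda with Rao's F approximation) is run on the
#' retained scores. With a single retained component the statistic reduces
#' exactly to the one-way ANOVA F.
#'
#' @param Xa,Xb Pre-processed intensity matrices of the two groups (same
#'   feature axis).
#' @param variance_target PCA cumulative-variance target.
#' @param n_components Optional override of the retained component count.
#' @return List of class `group_test`: `statistic` (approximate F),
#'   `kind = "Wilks-lambda-F"`, `wilks` (lambda itself), `df` (numerator,
#'   denominator), `p_value`, `n_components`.
#' @export
manova_pca <- function(Xa, Xb, variance_target = 0.95, n_components = NULL) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  stopifnot(nrow(Xa) >= 1, nrow(Xb) >= 1, ncol(Xa) == ncol(Xb))
  X <- rbind(Xa, Xb)
  g <- factor(rep(c("A", "B"), c(nrow(Xa), nrow(Xb))))
  pca <- fit_pca(X, if (is.null(n_components)) variance_target else 1)
  k <- if (is.null(n_components)) pca$n_components
       else min(n_components, ncol(pca$rotation))
  if (k > nrow(X) - 2L)
    stop("retained components exceed the pooled error degrees of freedom; ",
         "lower variance_target or n_components")
  S <- predict(pca, X)[, seq_len(k), drop = FALSE]

  if (k == 1L) {
    res <- stats::oneway.test(S[, 1] ~ g, var.equal = TRUE)
    out <- list(statistic = unname(res$statistic), kind = "Wilks-lambda-F",
                wilks = 1 / (1 + unname(res$statistic) *
                               res$parameter[[1]] / res$parameter[[2]]),
                df = unname(unlist(res$parameter)),
                p_value = res$p.value, n_components = 1L)
  } else {
    fit <- stats::manova(S ~ g)
    tab <- summary(fit, test = "Wilks")$stats
    out <- list(statistic = tab[1, "approx F"], kind = "Wilks-lambda-F",
                wilks = tab[1, "Wilks"],
                df = c(tab[1, "num Df"], tab[1, "den Df"]),
                p_value = tab[1, "Pr(>F)"], n_components = k)
  }
  structure(out, class = "group_test")
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided t-test directly from published group means, SDs
#' and sizes — the situation when comparing against a paper's demographic
#' table with no raw data. Welch (unequal variances, Welch-Satterthwaite
#' df) or pooled-variance variants.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List of class `group_test`: `statistic`, `kind = "t"`, `df`,
#'   `p_value`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    p <- if (mean1 == mean2) 1 else 0
    return(structure(list(statistic = if (p == 1) 0 else Inf, kind = "t",
                          df = n1 + n2 - 2, p_value = p),
                     class = "group_test"))
  }
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  structure(list(statistic = t, kind = "t", df = df,
                 p_value = 2 * stats::pt(-abs(t), df)),
            class = "group_test")
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; df = (r-1)(c-1) after optionally dropping
#' all-zero rows and columns (categories unobserved in both groups carry
#' no information and would make expected counts degenerate).
#'
#' @param counts Contingency matrix of non-negative integer counts.
#' @param drop_empty Drop all-zero rows/columns before testing.
#' @return List of class `group_test`: `statistic`, `kind =
#'   "chi-squared"`, `df`, `p_value`, `table` (as tested).
#' @export
pearson_chi2 <- function(counts, drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (drop_empty) {
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table after dropping empty categories")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a marginal total is zero")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(res$statistic), kind = "chi-squared",
                 df = unname(res$parameter), p_value = res$p.value,
                 table = counts),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  df <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s test: statistic = %.4g, df = %s, p = %.4g\n",
              x$kind, x$statistic, df, x$p_value))
  invisible(x)
}
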