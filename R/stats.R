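#' Normality test of a sample (Kolmogorov-Smirnov family)
#'
#' `"lilliefors"` (default) tests against a normal with parameters estimated
#' from the sample, with the Lilliefors correction of the null distribution
#' — the behaviour of common statistics packages when "K-S normality" is
#' requested. `"classical"` runs the plain one-sample K-S against
#' `N(mean(x), sd(x))` without the correction (anti-conservative; provided
#' for comparison).
#'
#' @param x Numeric sample; n >= 4 (lilliefors) or n >= 3 (classical),
#'   non-constant.
#' @param method `"lilliefors"` or `"classical"`.
#' @return List with `statistic`, `p_value`, `method`, `n`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "classical")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (anyNA(x)) stop("sample contains NA")
  nmin <- if (method == "lilliefors") 4L else 3L
  if (length(x) < nmin) stop(sprintf("need at least %d observations", nmin))
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  if (method == "lilliefors") {
    t <- nortest::lillie.test(x)
  } else {
    t <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(t$statistic), p_value = unname(t$p.value),
       method = method, n = length(x))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided, with the exact distribution when the effective sample size
#' (zero differences dropped) is at most 25 and there are no ties in the
#' absolute differences, otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return List with `statistic` (V), `p_value`, `n_effective`, `exact`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  if (anyNA(d)) stop("pairs contain NA")
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero: test degenerate")
  if (length(d) < 5) stop("need at least 5 non-zero paired differences")
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  t <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(t$statistic), p_value = t$p.value,
       n_effective = length(d), exact = exact)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; exact p-value for small tie-free samples,
#' otherwise the t-approximation (the AS89 path of [stats::cor.test()]).
#'
#' @param a,b Equal-length numeric vectors, n >= 5, neither constant.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 5) stop("need at least 5 observations")
  if (anyNA(a) || anyNA(b)) stop("vectors contain NA")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant vector: rank correlation undefined")
  ties <- anyDuplicated(a) > 0 || anyDuplicated(b) > 0
  t <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                        exact = !ties))
  list(rho = unname(t$estimate), p_value = t$p.value, n = length(a))
}

#' Correlation table of TCP against the plan indices
#'
#' Spearman rho (and p-values) of each TCP column against each of the six
#' plan-level indices, the cohort-table analogue of a published
#' TCP-vs-index correlation table.
#'
#' @param cohort Data frame with the index columns (`ioe_h_density`,
#'   `ioe_h_plain`, `ioe_c_density`, `ioe_c_plain`, `hi_mean`, `ci_mean`)
#'   and one or more `tcp_*` columns; no missing values.
#' @param tcp_cols Names of the TCP columns; default every column starting
#'   with `tcp`.
#' @param index_cols Names of the index columns.
#' @return An object of class `correlation_report` with matrices `rho` and
#'   `p_value` (rows = TCP columns, columns = indices).
#' @export
correlation_report <- function(cohort,
                               tcp_cols = grep("^tcp", names(cohort), value = TRUE),
                               index_cols = c("ioe_h_density", "ioe_h_plain",
                                              "ioe_c_density", "ioe_c_plain",
                                              "hi_mean", "ci_mean")) {
  cohort <- as.data.frame(cohort)
  need <- c(tcp_cols, index_cols)
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop(sprintf("cohort table lacks column(s): %s", paste(missing, collapse = ", ")))
  if (anyNA(cohort[need])) stop("cohort table has missing values in compared columns")
  if (!length(tcp_cols)) stop("no TCP columns found")
  rho <- p <- matrix(NA_real_, length(tcp_cols), length(index_cols),
                     dimnames = list(tcp_cols, index_cols))
  for (i in seq_along(tcp_cols)) for (j in seq_along(index_cols)) {
    s <- spearman_correlation(cohort[[tcp_cols[i]]], cohort[[index_cols[j]]])
    rho[i, j] <- s$rho
    p[i, j] <- s$p_value
  }
  structure(list(rho = rho, p_value = p, n = nrow(cohort)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> Spearman rho, n = %d\n", x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' Cohort-level statistical battery
#'
#' The full comparison pipeline over a cohort of plan evaluations:
#' normality of every compared column, paired Wilcoxon tests of the
#' density-weighted IOE against its plain form and against the conventional
#' mean (for H and C), and the TCP-vs-index Spearman table.
#'
#' @param cohort Cohort data frame (see [correlation_report()]).
#' @param alpha Significance threshold (default 0.05).
#' @return List with `normality` (data frame), `comparisons` (data frame)
#'   and `correlations` (a [correlation_report()]).
#' @export
cohort_statistics <- function(cohort, alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  idx <- c("ioe_h_density", "ioe_h_plain", "hi_mean",
           "ioe_c_density", "ioe_c_plain", "ci_mean")
  norm <- do.call(rbind, lapply(idx, function(cl) {
    k <- ks_normality(cohort[[cl]])
    data.frame(column = cl, statistic = k$statistic, p_value = k$p_value,
               normal = k$p_value >= alpha)
  }))
  pairs <- list(c("ioe_h_density", "ioe_h_plain"), c("ioe_h_density", "hi_mean"),
                c("ioe_h_plain", "hi_mean"),
                c("ioe_c_density", "ioe_c_plain"), c("ioe_c_density", "ci_mean"),
                c("ioe_c_plain", "ci_mean"))
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    w <- tryCatch(wilcoxon_paired(cohort[[pr[1]]], cohort[[pr[2]]]),
                  error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    data.frame(a = pr[1], b = pr[2], statistic = w$statistic,
               p_value = w$p_value,
               significant = !is.na(w$p_value) && w$p_value < alpha)
  }))
  list(normality = norm, comparisons = comp,
       correlations = correlation_report(cohort))
}
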