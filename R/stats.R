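#' Adjust p-values for multiple comparisons
#'
#' Holm step-down (sequential Bonferroni) or Benjamini-Hochberg step-up
#' (q-values), order-preserving with respect to the input indexing.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` or `"bh"`.
#' @return Adjusted p-values aligned with `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

test_result_row <- function(test, factor, statistic, value, p,
                            p_adjusted = NA_real_, adjustment = "none",
                            n = NA_integer_, note = "") {
  data.frame(test = test, factor = factor, statistic = statistic,
             value = unname(value), p = unname(p),
             p_adjusted = p_adjusted, adjustment = adjustment,
             n = paste(n, collapse = "/"), note = note,
             stringsAsFactors = FALSE)
}

#' Normality-gated group comparison
#'
#' Reproduces the gated testing pattern used throughout the analysis
#' tables: a Shapiro-Wilk test on pooled within-group residuals decides the
#' branch. When residuals are compatible with normality (p >= `alpha_gate`),
#' parametric tests are used (Welch two-sample t, one-sample t against
#' zero, or Welch ANOVA omnibus plus pairwise Welch t); otherwise
#' nonparametric analogues (Wilcoxon rank-sum with continuity correction,
#' Wilcoxon signed-rank, or Kruskal-Wallis plus pairwise Wilcoxon). All
#' tests are two-sided; pairwise follow-ups are Holm-corrected. When ties
#' make the exact Wilcoxon distribution unavailable, the normal
#' approximation with continuity correction is used and noted.
#'
#' @param groups For `design = "two_sample"`: list of two numeric vectors.
#'   For `"one_sample_vs_zero"`: a single numeric vector (or list of one).
#'   For `"k_sample"`: list of k numeric vectors (named if possible).
#' @param design `"two_sample"`, `"one_sample_vs_zero"`, or `"k_sample"`.
#' @param alpha_gate Normality-gate level (default 0.05).
#' @return A `gated_result`: data frame of test rows (Shapiro gate first),
#'   with attribute `branch` (`"parametric"`/`"nonparametric"`).
#' @export
normality_gated_compare <- function(groups,
                                    design = c("two_sample",
                                               "one_sample_vs_zero",
                                               "k_sample"),
                                    alpha_gate = 0.05) {
  design <- match.arg(design)
  if (!is.list(groups)) groups <- list(groups)
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("each sample needs n >= 3", call. = FALSE)
  }
  ns <- vapply(groups, length, integer(1))
  resid <- unlist(lapply(groups, function(g) g - mean(g)))
  sw <- stats::shapiro.test(resid)
  rows <- test_result_row("Shapiro-Wilk normality test", "pooled residuals",
                          "W", sw$statistic, sw$p.value, n = sum(ns))
  normal <- sw$p.value >= alpha_gate
  branch <- if (normal) "parametric" else "nonparametric"

  wilcox_row <- function(x, y = NULL, label, mu = 0) {
    wt <- tryCatch(
      stats::wilcox.test(x, y, mu = mu, correct = TRUE),
      warning = function(w) {
        res <- suppressWarnings(stats::wilcox.test(x, y, mu = mu,
                                                   correct = TRUE))
        attr(res, "tie_note") <- "ties: normal approximation used"
        res
      }
    )
    nm <- if (is.null(y)) "Wilcoxon signed rank test" else
      "Wilcoxon rank sum test with continuity correction"
    test_result_row(nm, label, names(wt$statistic), wt$statistic, wt$p.value,
                    n = c(length(x), length(y)),
                    note = attr(wt, "tie_note") %||% "")
  }

  if (design == "two_sample") {
    if (length(groups) != 2) stop("two_sample needs two groups",
                                  call. = FALSE)
    x <- groups[[1]]; y <- groups[[2]]
    rows <- rbind(rows, if (normal) {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      test_result_row("Welch Two Sample t-test", "group", "t", tt$statistic,
                      tt$p.value, n = ns)
    } else {
      wilcox_row(x, y, "group")
    })
  } else if (design == "one_sample_vs_zero") {
    x <- groups[[1]]
    rows <- rbind(rows, if (normal) {
      tt <- stats::t.test(x, mu = 0)
      test_result_row("One Sample t test", "difference from 0", "t",
                      tt$statistic, tt$p.value, n = ns)
    } else {
      wilcox_row(x, label = "difference from 0")
    })
  } else {
    k <- length(groups)
    if (k < 3) stop("k_sample expects >= 3 groups", call. = FALSE)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
    vals <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), ns), levels = names(groups))
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    if (normal) {
      om <- stats::oneway.test(vals ~ fac, var.equal = FALSE)
      rows <- rbind(rows, test_result_row(
        "Welch one-way ANOVA", "all groups", "F", om$statistic, om$p.value,
        n = ns))
      pw <- lapply(pairs, function(pr) {
        tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]],
                            var.equal = FALSE)
        test_result_row("Welch Two Sample t-test",
                        paste(pr, collapse = " vs "), "t", tt$statistic,
                        tt$p.value, n = ns[pr])
      })
    } else {
      kw <- stats::kruskal.test(vals, fac)
      rows <- rbind(rows, test_result_row(
        "Kruskal-Wallis rank sum test", "all groups",
        "Kruskal-Wallis chi-squared", kw$statistic, kw$p.value, n = ns))
      pw <- lapply(pairs, function(pr) {
        wilcox_row(groups[[pr[1]]], groups[[pr[2]]],
                   paste(pr, collapse = " vs "))
      })
    }
    pw <- do.call(rbind, pw)
    pw$p_adjusted <- adjust_pvalues(pw$p, "holm")
    pw$adjustment <- "holm"
    rows <- rbind(rows, pw)
  }
  rownames(rows) <- NULL
  attr(rows, "branch") <- branch
  class(rows) <- c("gated_result", "data.frame")
  rows
}

#' Two-way mixed ANOVA
#'
#' One between-subject factor and one within-subject (repeated) factor,
#' with the standard subject-error partitioning: the between effect is
#' tested against between-subject error, the within effect and the
#' interaction against the subject-by-within error stratum. Requires a
#' balanced complete design (every subject measured at every within level
#' exactly once).
#'
#' @param data Long-format data frame.
#' @param subject,between,within,response Column names.
#' @return Data frame with rows `between`, `within`, `interaction`:
#'   `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data, subject = "subject", between = "between",
                        within = "within", response = "response") {
  df <- data.frame(
    subject = factor(data[[subject]]),
    between = factor(data[[between]]),
    within = factor(data[[within]]),
    y = data[[response]]
  )
  tab <- table(df$subject, df$within)
  if (any(tab != 1)) {
    stop("design must be balanced and complete (one observation per ",
         "subject x within-level cell)", call. = FALSE)
  }
  fit <- stats::aov(y ~ between * within + Error(subject / within),
                    data = df)
  sm <- summary(fit)
  s_between <- sm[["Error: subject"]][[1]]
  s_within <- sm[["Error: subject:within"]][[1]]
  ss_tol <- 1e-10 * (sum(df$y^2) + 1)
  grab <- function(stratum, term) {
    i <- trimws(rownames(stratum)) == term
    f <- stratum[i, "F value"]
    p <- stratum[i, "Pr(>F)"]
    # a term whose sum of squares is numerically zero explains nothing:
    # report F = 0 instead of a 0/0 ratio of rounding noise
    if (stratum[i, "Sum Sq"] <= ss_tol) {
      f <- 0
      p <- 1
    }
    c(F = f, df1 = stratum[i, "Df"],
      df2 = stratum[trimws(rownames(stratum)) == "Residuals", "Df"],
      p = p)
  }
  out <- rbind(
    between = grab(s_between, "between"),
    within = grab(s_within, "within"),
    interaction = grab(s_within, "between:within")
  )
  as.data.frame(out)
}
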