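# Group statistics for labelling metrics: IQR outlier flagging, group
# comparisons (Tukey HSD / Student t), Benjamini-Hochberg correction.

#' Flag outliers by the 1.5 x IQR rule
#'
#' Flags values below `Q1 - 1.5*IQR` or above `Q3 + 1.5*IQR`. Quartiles use
#' linear interpolation (R's default type-7 convention). With fewer than 4
#' non-missing values the quartiles are too unstable to fence on, so
#' nothing is flagged and a warning is issued.
#'
#' @param values Numeric vector.
#' @return Logical vector, `TRUE` for outliers (`NA` in, `NA` out).
#' @examples
#' flag_outliers_iqr(c(1, 2, 3, 4, 100))
#' @export
flag_outliers_iqr <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  if (sum(!is.na(values)) < 4L) {
    warning("fewer than 4 values; no outliers flagged", call. = FALSE)
    return(ifelse(is.na(values), NA, FALSE))
  }
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - 1.5 * iqr | values > q[2L] + 1.5 * iqr
}

#' Compare groups of a labelling metric
#'
#' `"anova_tukey"` runs one-way ANOVA followed by Tukey's honestly
#' significant difference test over all group pairs. `"t_two_sided"` and
#' `"t_one_sided"` run the pooled-variance (Student) two-group t-test; the
#' one-sided direction must be given explicitly via `alternative` (the
#' hypothesis, e.g. `"less"` for group1 < group2, is a design choice, never
#' inferred from the data).
#'
#' @param values Numeric vector of the metric.
#' @param groups Group labels, same length; comparison order follows factor
#'   levels (or order of first appearance).
#' @param method `"anova_tukey"`, `"t_two_sided"` or `"t_one_sided"`.
#' @param alternative For `"t_one_sided"`: `"less"` or `"greater"`.
#' @return `data.frame` with one row per comparison: `group1`, `group2`,
#'   `estimate` (mean difference group1 - group2), `statistic`, `p_value`,
#'   `adjusted_p` (Tukey-adjusted; `NA` for t-tests), `method`. For
#'   `"anova_tukey"` the overall F and its p-value are attached as
#'   attributes `"anova_f"` and `"anova_p"`.
#' @export
compare_groups <- function(values, groups,
                           method = c("anova_tukey", "t_two_sided",
                                      "t_one_sided"),
                           alternative = NULL) {
  method <- match.arg(method)
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' must have equal length", call. = FALSE)
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- if (is.factor(groups)) droplevels(groups[ok]) else
    factor(groups[ok], levels = unique(groups[ok]))
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 values for variance-based tests",
         call. = FALSE)
  }

  if (method == "anova_tukey") {
    fit <- aov(values ~ g)
    tk <- TukeyHSD(fit)$g
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    out <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                      estimate = tk[, "diff"], statistic = tk[, "diff"],
                      p_value = tk[, "p adj"], adjusted_p = tk[, "p adj"],
                      method = method, row.names = NULL,
                      stringsAsFactors = FALSE)
    an <- summary(fit)[[1L]]
    attr(out, "anova_f") <- an[1L, "F value"]
    attr(out, "anova_p") <- an[1L, "Pr(>F)"]
    return(out)
  }

  if (length(sizes) != 2L) {
    stop(sprintf("method '%s' requires exactly 2 groups, got %d",
                 method, length(sizes)), call. = FALSE)
  }
  if (method == "t_one_sided") {
    if (is.null(alternative) || !alternative %in% c("less", "greater")) {
      stop("one-sided t-test requires alternative = 'less' or 'greater'",
           call. = FALSE)
    }
  } else {
    alternative <- "two.sided"
  }
  lev <- levels(g)
  tt <- t.test(values[g == lev[1L]], values[g == lev[2L]],
               var.equal = TRUE, alternative = alternative)
  data.frame(group1 = lev[1L], group2 = lev[2L],
             estimate = unname(diff(rev(tt$estimate))),
             statistic = unname(tt$statistic),
             p_value = tt$p.value, adjusted_p = NA_real_,
             method = method, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1, invariant
#' to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
#' @export
adjust_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}
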