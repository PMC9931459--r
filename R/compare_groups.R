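#' Between-group comparison tests
#'
#' Group comparisons used for the cohort characteristics table. Categorical
#' variables are tested with Pearson's chi-square on the group-by-level
#' contingency table (no continuity correction, so 2x2 tables match the
#' closed-form Pearson statistic). Continuous variables use the two-sided
#' Wilcoxon rank-sum test for two groups (normal approximation with
#' continuity correction, as ties make the exact distribution unavailable)
#' and its k-sample extension, the Kruskal-Wallis test, for more than two.
#'
#' @param values Variable to compare (numeric for `"continuous"`, any
#'   discrete type for `"categorical"`).
#' @param group Group labels; k >= 2 non-empty groups.
#' @param kind `"categorical"` or `"continuous"`.
#' @return List with `p_value`, `statistic`, `method`.
#' @examples
#' compareGroups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
#'               "continuous")$p_value
#' @export
compareGroups <- function(values, group, kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  group <- as.factor(group)
  if (length(values) != length(group)) {
    stop_validation("`values` and `group` must have the same length")
  }
  counts <- table(group)
  if (any(counts == 0)) {
    stop_validation("group(s) with zero subjects: ",
                    paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (nlevels(group) < 2) stop_validation("need at least 2 groups")
  if (kind == "categorical") {
    tab <- table(group, values)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "Pearson chi-square")
  } else {
    if (!is.numeric(values)) {
      stop_validation("continuous comparison needs numeric `values`")
    }
    if (nlevels(group) == 2) {
      ht <- suppressWarnings(
        stats::wilcox.test(values ~ group, exact = FALSE, correct = TRUE))
      list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
           method = "Wilcoxon rank-sum")
    } else {
      ht <- stats::kruskal.test(values, group)
      list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
           method = "Kruskal-Wallis")
    }
  }
}
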