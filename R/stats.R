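#' Group comparison following the reporting conventions of EPS experiments
#'
#' Two groups are compared with an equal-variance Student's t-test; three or
#' more groups with one-way ANOVA followed by either Tukey's all-pairs or
#' Dunnett's many-to-one multiple comparison test (Dunnett requires a named
#' control group). Group means and standard errors are always reported, and
#' significance is starred at p < 0.05 (`*`) and p < 0.01 (`**`).
#'
#' Dunnett adjusted p-values come from the multivariate t distribution
#' (through the multcomp package); its quasi-random integration is run under
#' a fixed internal seed so results are reproducible.
#'
#' @param data `data.frame` with columns `value` and `group`, or a named
#'   list of numeric vectors.
#' @param design `"auto"` (t-test for two groups, one-way ANOVA otherwise),
#'   `"two_group"` or `"one_way"`.
#' @param posthoc `"tukey"` or `"dunnett"` (one-way designs only).
#' @param control control group name; required for Dunnett.
#' @param alpha significance level (0.05, the conventional threshold).
#' @return object of class `comparison_result`: list with `design`, `test`,
#'   `group_stats` (mean, SE, n per group), `statistic` (t or F), `df`,
#'   `comparisons` (`data.frame` of contrasts with unadjusted and adjusted
#'   p-values, significance flags and stars) and `alpha`.
#' @export
compare_groups <- function(data, design = c("auto", "two_group", "one_way"),
                           posthoc = c("tukey", "dunnett"), control = NULL,
                           alpha = 0.05) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) stopf("group list must be named")
    data <- data.frame(value = unlist(data, use.names = FALSE),
                       group = rep(names(data), lengths(data)))
  }
  if (!all(c("value", "group") %in% names(data)))
    stopf("'data' must have columns 'value' and 'group'")
  data <- data[complete.cases(data[, c("value", "group")]), ]
  data$group <- as.character(data$group)
  ns <- table(data$group)
  if (length(ns) < 2) stopf("at least 2 groups are required")
  if (any(ns < 2))
    stopf("every group needs n >= 2 (got n = %d for '%s')",
          min(ns), names(ns)[which.min(ns)])
  if (design == "auto") design <- if (length(ns) == 2) "two_group" else "one_way"
  if (design == "two_group" && length(ns) != 2)
    stopf("'two_group' design requires exactly 2 groups")
  group_stats <- do.call(rbind, lapply(split(data$value, data$group),
    function(v) data.frame(mean = mean(v), se = standard_error(v), n = length(v))))
  group_stats <- data.frame(group = rownames(group_stats), group_stats,
                            row.names = NULL)

  if (design == "two_group") {
    g <- split(data$value, data$group)
    tt <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    p <- tt$p.value
    comparisons <- data.frame(
      comparison = paste(names(g)[1], "-", names(g)[2]),
      estimate = mean(g[[1]]) - mean(g[[2]]),
      p_unadjusted = p, p_adjusted = p,
      significant = p < alpha, stars = p_stars(p))
    return(structure(list(design = "two_group", test = "t",
                          group_stats = group_stats,
                          statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          comparisons = comparisons, alpha = alpha),
                     class = "comparison_result"))
  }

  levels_order <- sort(unique(data$group))
  if (posthoc == "dunnett") {
    if (is.null(control)) stopf("Dunnett's test requires a 'control' group")
    if (!control %in% levels_order)
      stopf("control group '%s' not present", control)
    levels_order <- c(control, setdiff(levels_order, control))
  }
  data$group <- factor(data$group, levels = levels_order)
  fit <- stats::aov(value ~ group, data = data)
  ftab <- summary(fit)[[1]]
  fstat <- ftab[["F value"]][1]
  dfs <- ftab[["Df"]]
  pw <- with(data, stats::pairwise.t.test(value, group, p.adjust.method = "none",
                                          pool.sd = TRUE))$p.value
  unadj <- function(a, b) {
    if (!is.null(pw) && a %in% rownames(pw) && b %in% colnames(pw) &&
        !is.na(pw[a, b])) pw[a, b] else pw[b, a]
  }
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    comparisons <- data.frame(
      comparison = paste(vapply(parts, `[`, "", 1), "-", vapply(parts, `[`, "", 2)),
      estimate = tk[, "diff"],
      p_unadjusted = vapply(parts, function(p) unadj(p[1], p[2]), numeric(1)),
      p_adjusted = tk[, "p adj"], row.names = NULL)
    test <- "anova_tukey"
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- with_seed(20231L, summary(gl))
    est <- sm$test$coefficients
    padj <- as.numeric(sm$test$pvalues)
    parts <- strsplit(names(est), " - ", fixed = TRUE)
    comparisons <- data.frame(
      comparison = paste(vapply(parts, `[`, "", 1), "-", vapply(parts, `[`, "", 2)),
      estimate = as.numeric(est),
      p_unadjusted = vapply(parts, function(p) unadj(p[1], p[2]), numeric(1)),
      p_adjusted = padj, row.names = NULL)
    test <- "anova_dunnett"
  }
  comparisons$significant <- comparisons$p_adjusted < alpha
  comparisons$stars <- p_stars(comparisons$p_adjusted)
  structure(list(design = "one_way", test = test, group_stats = group_stats,
                 statistic = fstat, df = dfs, comparisons = comparisons,
                 alpha = alpha, control = control),
            class = "comparison_result")
}

p_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s), statistic = %.4g\n",
              x$design, x$test, x$statistic))
  cat("Group means +/- SE:\n")
  print(x$group_stats, row.names = FALSE)
  cat("Comparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
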