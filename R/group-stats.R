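#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for `m` comparisons.
#'
#' @param p raw p-values.
#' @param m number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) pmin(1, m * p)

group_summary_table <- function(values, groups) {
  sp <- split(values, groups)
  data.frame(group = names(sp),
             n = lengths(sp),
             mean = vapply(sp, mean, 0),
             se = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare group means (t-test / one-way / two-way ANOVA)
#'
#' Reports per-group mean +/- SE and the test appropriate to the design:
#' an unpaired equal-variance t-test for two groups; one-way ANOVA with
#' Bonferroni-corrected pairwise post hoc comparisons for multiple groups
#' (pairwise flags are "protected" — significant only when the omnibus
#' test is also below `alpha`); fixed-effects two-way ANOVA with
#' interaction for factorial designs. The `alpha` threshold is used for
#' flagging only.
#'
#' @param data a data.frame of per-cell measurements.
#' @param value name of the measurement column.
#' @param group name of the group-label column.
#' @param design `"two_group"`, `"one_way"` or `"two_way"`.
#' @param factor2 second factor column (two-way designs).
#' @param alpha significance threshold for flagging.
#' @return a `group_report`: `summary` (mean +/- SE per group),
#'   `omnibus` (statistic, df, p), `comparisons` (pairwise raw and
#'   Bonferroni-adjusted p-values with significance flags).
#' @export
compare_means <- function(data, value, group = "group",
                          design = c("two_group", "one_way", "two_way"),
                          factor2 = NULL, alpha = 0.05) {
  design <- match.arg(design)
  if (!all(c(value, group) %in% names(data)))
    stop("data must contain columns '", value, "' and '", group, "'")
  v <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("at least two groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  summ <- group_summary_table(v, g)

  if (design == "two_group") {
    if (k != 2L) stop("two_group design requires exactly 2 groups")
    tt <- stats::t.test(v ~ g, var.equal = TRUE)
    comparisons <- data.frame(
      comparison = paste(levels(g)[1L], "vs", levels(g)[2L]),
      statistic = unname(tt$statistic), p = tt$p.value,
      p_adj = tt$p.value, significant = tt$p.value < alpha,
      stringsAsFactors = FALSE)
    omnibus <- list(test = "t", statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value)
  } else if (design == "one_way") {
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1L]]
    omnibus <- list(test = "one-way ANOVA", statistic = an[1L, "F value"],
                    df = c(an[1L, "Df"], an[2L, "Df"]), p = an[1L, "Pr(>F)"])
    prs <- utils::combn(levels(g), 2L)
    m <- ncol(prs)
    raw <- vapply(seq_len(m), function(j) {
      sel <- g %in% prs[, j]
      stats::t.test(v[sel] ~ droplevels(g[sel]), var.equal = TRUE)$p.value
    }, 0)
    padj <- bonferroni_adjust(raw, m)
    comparisons <- data.frame(
      comparison = paste(prs[1L, ], "vs", prs[2L, ]),
      p = raw, p_adj = padj,
      significant = omnibus$p < alpha & padj < alpha,
      stringsAsFactors = FALSE)
  } else {
    if (is.null(factor2) || !factor2 %in% names(data))
      stop("two_way design requires 'factor2'")
    g2 <- droplevels(factor(data[[factor2]][ok]))
    fit <- stats::aov(v ~ g * g2)
    an <- summary(fit)[[1L]]
    omnibus <- list(test = "two-way ANOVA",
                    terms = rownames(an),
                    statistic = an[, "F value"], p = an[, "Pr(>F)"])
    comparisons <- data.frame(
      comparison = trimws(rownames(an)[-nrow(an)]),
      p = an[-nrow(an), "Pr(>F)"],
      p_adj = an[-nrow(an), "Pr(>F)"],
      significant = an[-nrow(an), "Pr(>F)"] < alpha,
      stringsAsFactors = FALSE)
  }
  structure(list(design = design, summary = summ, omnibus = omnibus,
                 comparisons = comparisons, alpha = alpha),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %s (alpha = %g)\n", x$design, x$alpha))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.3g +/- %.3g (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$se[i], x$summary$n[i]))
  if (!is.null(x$omnibus$p))
    cat(sprintf("  omnibus p = %s\n",
                paste(signif(x$omnibus$p, 3), collapse = ", ")))
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("  %s: p_adj = %.3g%s\n", x$comparisons$comparison[i],
                x$comparisons$p_adj[i],
                if (isTRUE(x$comparisons$significant[i])) " *" else ""))
  invisible(x)
}

#' Chi-square comparison of per-cell categorical flags
#'
#' Builds the flag-by-group contingency table (e.g. cells exhibiting DADs,
#' waves, or embers per group) and applies the classic chi-square test,
#' without Yates continuity correction by default.
#'
#' @param x either a contingency matrix (groups in rows) or a data.frame.
#' @param flag flag column name (when `x` is a data.frame); values are
#'   coerced to logical/factor.
#' @param group group column name (when `x` is a data.frame).
#' @param correct apply Yates continuity correction.
#' @return a `prop_report`: `table`, `statistic`, `df`, `p`.
#' @export
compare_proportions <- function(x, flag = NULL, group = "group",
                                correct = FALSE) {
  if (is.matrix(x)) {
    tab <- x
  } else {
    if (is.null(flag) || !all(c(flag, group) %in% names(x)))
      stop("need 'flag' and 'group' columns")
    tab <- table(x[[group]], x[[flag]])
  }
  if (any(rowSums(tab) == 0))
    stop("group(s) with zero cells: ",
         paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 correct = correct),
            class = "prop_report")
}

#' @export
print.prop_report <- function(x, ...) {
  cat(sprintf("<prop_report> chi-square = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p,
              if (x$correct) " (Yates-corrected)" else ""))
  invisible(x)
}
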