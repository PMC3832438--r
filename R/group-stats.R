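#' Summarize recanalization reports by dose group
#'
#' Per-group mean and sample standard deviation (n - 1 denominator) of the
#' thrombolysis score, the number of animals achieving effective
#' recanalization, and their times to recanalization.
#'
#' @param reports list of [analyze_flow_trace()] reports
#' @param dose numeric vector of doses, one per report
#' @param group optional group labels, one per report; defaults to the dose
#' @return a data frame of class `dose_group_summary` with one row per
#'   group and a list-column `times_to_recanalization_min`
#' @export
summarize_doses <- function(reports, dose, group = NULL) {
  stopifnot(length(reports) == length(dose))
  group <- group %||% as.character(dose)
  scores <- vapply(reports, function(r) r$score_pct, numeric(1))
  recan <- vapply(reports, function(r) r$effective_recanalization_time_min,
                  numeric(1))
  levels_ <- unique(group)
  rows <- lapply(levels_, function(g) {
    sel <- group == g
    n <- sum(sel)
    sdv <- if (n >= 2) stats::sd(scores[sel]) else {
      warning(sprintf("group %s has n = 1; SD not defined", g), call. = FALSE)
      NA_real_
    }
    times <- recan[sel][!is.na(recan[sel])]
    data.frame(group = g, dose = dose[sel][1], n = n,
               mean_score_pct = mean(scores[sel]), sd_score_pct = sdv,
               n_effective_recanalization = length(times),
               times_to_recanalization_min = I(list(times)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_group_summary", "data.frame")
  out
}

#' Compare dose groups
#'
#' Group comparison as used for the dose-response analyses: one-way ANOVA
#' followed by Tukey HSD pairwise contrasts for three or more groups; the
#' exact Mann-Whitney U test for exactly two groups (the nonparametric path
#' used for the hematology comparisons). Significance threshold 0.05.
#' Fully degenerate input (every observation identical) yields p = 1 by
#' convention.
#'
#' @param scores numeric outcome values
#' @param group group labels, one per score; each group needs n >= 2
#' @param control label of the reference group for the reported pairwise
#'   contrasts; defaults to the first group
#' @return a list of class `group_comparison` with elements `method`,
#'   `statistic`, `p_value`, `pairwise` (Tukey table or `NULL`) and
#'   `significant`
#' @export
compare_groups <- function(scores, group, control = NULL) {
  group <- as.character(group)
  levels_ <- unique(group)
  if (length(levels_) < 2)
    stop_with("thrombolyzer_invalid_input", "need at least two groups")
  if (any(table(group) < 2))
    stop_with("thrombolyzer_invalid_input", "each group needs n >= 2")
  control <- control %||% levels_[1]

  if (length(unique(scores)) == 1L) {
    out <- list(method = "degenerate", statistic = NA_real_, p_value = 1,
                pairwise = NULL, significant = FALSE)
    class(out) <- "group_comparison"
    return(out)
  }

  if (length(levels_) == 2L) {
    w <- stats::wilcox.test(scores[group == levels_[2]],
                            scores[group == levels_[1]], exact = TRUE)
    out <- list(method = "mann-whitney", statistic = unname(w$statistic),
                p_value = w$p.value, pairwise = NULL,
                significant = w$p.value < 0.05)
  } else {
    g <- factor(group, levels = levels_)
    fit <- stats::aov(scores ~ g)
    an <- summary(fit)[[1]]
    pval <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    tab <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
    vs_control <- grepl(paste0("(^", control, "-)|(-", control, "$)"),
                        tab$contrast)
    out <- list(method = "anova-tukey", statistic = an[["F value"]][1],
                p_value = pval, pairwise = tab,
                pairwise_vs_control = tab[vs_control, ],
                significant = pval < 0.05)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: p = %.4g%s\n", x$method, x$p_value,
              if (x$significant) " (significant at 0.05)" else ""))
  if (!is.null(x$pairwise_vs_control)) {
    cat("  contrasts vs control:\n")
    print(x$pairwise_vs_control, row.names = FALSE)
  }
  invisible(x)
}
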