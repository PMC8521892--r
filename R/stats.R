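## Cohort evaluation layer: score frequencies, group summaries, normality
## check, one-way ANOVA with Tukey post-hoc comparison.

#' Frequencies of congestive hepatic fibrosis scores
#'
#' Per-level counts and percentages of a cohort's CHFS grades (ordinal 0-4).
#' Display percentages are rounded to integers; the exact values are kept
#' alongside.
#'
#' @param chfs vector of scores in 0..4, or a data frame with a `chfs`
#'   column.
#' @return data frame with columns `chfs`, `n`, `percent` (exact) and
#'   `percent_display` (rounded to integer).
#' @examples
#' score_frequencies(rep(0:2, c(23, 16, 11)))  # 46%, 32%, 22%
#' @export
score_frequencies <- function(chfs) {
  if (is.data.frame(chfs)) chfs <- chfs$chfs
  if (length(chfs) == 0L) stop("empty cohort", call. = FALSE)
  if (anyNA(chfs) || !all(chfs %in% 0:4))
    stop("CHFS scores must lie in 0..4", call. = FALSE)
  lev <- sort(unique(chfs))
  n <- vapply(lev, function(l) sum(chfs == l), 0L)
  data.frame(chfs = lev, n = n,
             percent = 100 * n / length(chfs),
             percent_display = round(100 * n / length(chfs)))
}

#' Compare CFR or SLR across CHFS groups
#'
#' The fixed inferential procedure: per-group descriptive summaries (mean,
#' sd, median, IQR), a Kolmogorov-Smirnov normality check per group (against
#' a normal with the group's estimated mean and sd), one-way ANOVA, and all
#' pairwise Tukey-HSD-adjusted comparisons. The procedure never switches to
#' a nonparametric test on its own; when normality is rejected in any group
#' (KS p < 0.05) a warning is raised and the report flags it.
#'
#' @param records data frame with columns `chfs` and `cfr_percent` /
#'   `slr_percent` (see also the cohort CSV layout in [read_cohort_csv()]).
#' @param variable `"cfr"` or `"slr"`.
#' @return object of class `group_comparison`: list with `variable`,
#'   `groups` (data frame of descriptives + KS p), `anova` (`F`, `df1`,
#'   `df2`, `p`), `tukey` (data frame of pairwise differences and adjusted
#'   p), `normality_rejected`.
#' @export
group_compare <- function(records, variable = c("cfr", "slr")) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_percent")
  if (!is.data.frame(records) || is.null(records$chfs) || is.null(records[[col]]))
    stop("records must have columns 'chfs' and '", col, "'", call. = FALSE)
  x <- records[[col]]
  g <- factor(records$chfs)
  sizes <- table(g)
  if (length(sizes) < 2L)
    stop("need at least two CHFS groups", call. = FALSE)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("degenerate groups with fewer than 2 observations: CHFS ",
         paste(small, collapse = ", "), call. = FALSE)

  per_group <- do.call(rbind, lapply(levels(g), function(l) {
    v <- x[g == l]
    ks <- if (sd(v) > 0)
      suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v)))$p.value
    else NA_real_
    data.frame(chfs = l, n = length(v), mean = mean(v), sd = sd(v),
               median = median(v),
               iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
               ks_p = ks, stringsAsFactors = FALSE)
  }))

  if (all(tapply(x, g, sd) == 0))
    warning("all groups are constant; the ANOVA F statistic is undefined")
  fit <- aov(x ~ g)
  tab <- summary(fit)[[1]]
  f_stat <- tab[1, "F value"]
  p_val <- tab[1, "Pr(>F)"]

  tk <- TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)

  norm_rej <- any(per_group$ks_p < 0.05, na.rm = TRUE)
  if (norm_rej)
    warning("normality rejected (KS p < 0.05) in at least one group; ",
            "the ANOVA is still reported, interpret with care")

  structure(list(variable = variable, groups = per_group,
                 anova = list(F = f_stat, df1 = tab[1, "Df"],
                              df2 = tab[2, "Df"], p = p_val),
                 tukey = tukey, normality_rejected = norm_rej),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison of %s%% across CHFS groups\n\n",
              toupper(x$variable)))
  gp <- x$groups
  for (i in seq_len(nrow(gp)))
    cat(sprintf("  CHFS %s (n=%d): mean %.2f +/- %.2f, median %.2f (IQR %.2f), KS p=%s\n",
                gp$chfs[i], gp$n[i], gp$mean[i], gp$sd[i], gp$median[i],
                gp$iqr[i], format.pval(gp$ks_p[i], digits = digits)))
  cat(sprintf("\n  one-way ANOVA: F(%d, %d) = %.3f, p = %s\n",
              x$anova$df1, x$anova$df2, x$anova$F,
              format.pval(x$anova$p, digits = digits)))
  cat("  Tukey HSD pairwise comparisons:\n")
  tk <- x$tukey
  for (i in seq_len(nrow(tk)))
    cat(sprintf("    %s: diff %.2f, adjusted p = %s\n",
                tk$comparison[i], tk$diff[i],
                format.pval(tk$p_adj[i], digits = digits)))
  if (x$normality_rejected)
    cat("  note: KS normality rejected in at least one group\n")
  invisible(x)
}

#' Read / write a cohort table
#'
#' One row per animal: `animal_id`, `chfs`, `cfr_percent`, `slr_percent`,
#' optional `perisinusoidal_fibrosis`.
#'
#' @param path CSV file.
#' @param records cohort data frame.
#' @return `read_cohort_csv` returns the data frame; `write_cohort_csv` the
#'   path invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("animal_id", "chfs", "cfr_percent", "slr_percent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write a plain-text + CSV report of a group comparison
#'
#' @param comparison a [group_compare()] result.
#' @param path_txt,path_csv output files (either may be `NULL`).
#' @return invisibly, the comparison.
#' @export
write_comparison_report <- function(comparison, path_txt = NULL, path_csv = NULL) {
  stopifnot(inherits(comparison, "group_comparison"))
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w")
    sink(con); print(comparison); sink()
    close(con)
  }
  if (!is.null(path_csv)) {
    gp <- comparison$groups
    gp$anova_F <- comparison$anova$F
    gp$anova_p <- comparison$anova$p
    utils::write.csv(gp, path_csv, row.names = FALSE)
  }
  invisible(comparison)
}
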