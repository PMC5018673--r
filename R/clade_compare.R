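#' One-way ANOVA of a genus characteristic across major clades
#'
#' Non-phylogenetic comparison: standard one-way decomposition with
#' `F = (SSB / df_b) / (SSW / df_w)`, p-value from the F distribution and
#' effect size `R^2 = SSB / SST`. The fit is delegated to [stats::aov()];
#' Tukey's honestly-significant-difference pairwise comparisons
#' (Tukey-Kramer standard errors under unequal group sizes) come from
#' [stats::TukeyHSD()] on the same fit.
#'
#' @param values Numeric vector (typically a log10-scale characteristic).
#' @param groups Clade label per value (character or factor).
#' @return List of class `"clade_anova"`: `F`, `df_between`, `df_within`,
#'   `p_value`, `r_squared`, `group_means`, `group_n`, `tukey` (data.frame
#'   with `pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("degenerate group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0))
    stop("undefined F: zero within-group variance in every group",
         call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  ssb <- an[["Sum Sq"]][1L]; ssw <- an[["Sum Sq"]][2L]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  structure(list(
    F = an[["F value"]][1L],
    df_between = an[["Df"]][1L],
    df_within = an[["Df"]][2L],
    p_value = an[["Pr(>F)"]][1L],
    r_squared = ssb / (ssb + ssw),
    group_means = tapply(values, groups, mean),
    group_n = as.integer(sizes),
    tukey = tukey
  ), class = "clade_anova")
}

#' Tukey HSD pairwise comparisons across clades
#'
#' Convenience accessor returning only the pairwise table from
#' [one_way_anova()].
#'
#' @inheritParams one_way_anova
#' @return Data.frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  one_way_anova(values, groups)$tukey
}

#' @export
print.clade_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g, R^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p_value, x$r_squared))
  cat("Group means:\n")
  print(round(x$group_means, 3))
  cat("Tukey HSD:\n")
  tk <- x$tukey
  tk$diff <- sprintf("%.3f", tk$diff)
  tk$p_adj <- sprintf("%.4f", tk$p_adj)
  print(tk[, c("pair", "diff", "p_adj")], row.names = FALSE)
  invisible(x)
}

#' Load a genus-to-clade classification table
#'
#' Delimited text with columns `genus` and `clade`. Genera may be absent
#' (they are simply excluded from clade comparisons); a genus must not map
#' to two clades.
#'
#' @param path Path to the delimited file (`.csv` comma, else tab).
#' @return Named character vector mapping genus to clade.
#' @export
load_clade_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (!all(c("genus", "clade") %in% names(raw)))
    stop("clade table needs 'genus' and 'clade' columns", call. = FALSE)
  if (anyDuplicated(raw$genus))
    stop("genus mapped to more than one clade: ",
         paste(unique(raw$genus[duplicated(raw$genus)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(raw$clade, raw$genus)
}
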