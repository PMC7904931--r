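# Condition comparisons: one-way ANOVA + Tukey HSD per lipid system
# (all-pairs, with the vs-control and vs-aglycone families flagged) and a
# two-way ANOVA across lipid systems.

aglycone_of <- c(NOTHOFAGIN = "PHLORETIN", PHLORIZIN = "PHLORETIN",
                 G8 = "GENISTEIN", GLCRESVERATROL = "RESVERATROL")

#' Significance code for a p-value
#'
#' Star ladder used in the condition figures: `ns` (p >= 0.05), `*`
#' (p < 0.05), `**` (p < 0.01), `***` (p < 0.001), `****` (p < 0.0001).
#'
#' @param p Numeric p-value(s) in \[0, 1\].
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("field 'p': values must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

#' One-way ANOVA with Tukey's post-test
#'
#' Omnibus F-test across groups followed by all-pairs Tukey HSD
#' (Tukey--Kramer for unbalanced groups).  Comparisons against the control
#' group and between each glucoside and its aglycone are flagged.
#'
#' @param values Numeric replicate measurements.
#' @param groups Group labels (one per value).
#' @param control Label of the control group (flagged in the output).
#' @return A list with `f_statistic`, `p_omnibus`, and `comparisons`: a
#'   data.frame with `group_a`, `group_b`, `diff`, `p_value`,
#'   `significance_code`, `vs_control`, `vs_aglycone`.
#' @export
one_way_anova_tukey <- function(values, groups, control = "CONTROL") {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stopf("field 'groups': length must match 'values'")
  }
  tab <- table(groups)
  if (length(tab) < 2L) stopf("field 'groups': need at least 2 groups")
  if (any(tab < 2L)) {
    stopf("field 'groups': group '%s' has fewer than 2 replicates",
          names(tab)[tab < 2L][1])
  }
  d <- data.frame(y = as.numeric(values), g = factor(groups))
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  comp <- data.frame(group_a = vapply(pair, `[`, "", 1),
                     group_b = vapply(pair, `[`, "", 2),
                     diff = unname(tk[, "diff"]),
                     p_value = unname(tk[, "p adj"]),
                     stringsAsFactors = FALSE)
  comp$significance_code <- as.character(significance_code(comp$p_value))
  comp$vs_control <- comp$group_a == control | comp$group_b == control
  other <- ifelse(comp$group_a %in% names(aglycone_of), comp$group_a,
                  ifelse(comp$group_b %in% names(aglycone_of), comp$group_b,
                         NA_character_))
  comp$vs_aglycone <- !is.na(other) &
    (comp$group_a == unname(aglycone_of[other]) |
       comp$group_b == unname(aglycone_of[other]))
  list(f_statistic = an[["F value"]][1], p_omnibus = an[["Pr(>F)"]][1],
       comparisons = comp)
}

#' Two-way ANOVA across compounds and lipid systems
#'
#' Fixed crossed two-way ANOVA with interaction:
#' `value ~ compound * lipid_system`.
#'
#' @param data Data frame with columns `value`, `compound`, `lipid_system`.
#' @return A data.frame of effects (`compound`, `lipid_system`,
#'   `compound:lipid_system`) with `df`, `f_statistic`, `p_value`.
#' @export
two_way_anova <- function(data) {
  data <- as.data.frame(data)
  need <- c("value", "compound", "lipid_system")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("field 'data': missing column '%s'", miss[1])
  cells <- table(data$compound, data$lipid_system)
  if (any(cells == 0)) {
    stopf("empty design cell: compound '%s' x lipid system '%s'",
          rownames(cells)[which(cells == 0, arr.ind = TRUE)[1, 1]],
          colnames(cells)[which(cells == 0, arr.ind = TRUE)[1, 2]])
  }
  d <- data.frame(y = as.numeric(data$value),
                  compound = factor(data$compound),
                  lipid_system = factor(data$lipid_system))
  fit <- aov(y ~ compound * lipid_system, data = d)
  an <- summary(fit)[[1]]
  keep <- seq_len(nrow(an) - 1L)  # drop residuals row
  data.frame(effect = trimws(rownames(an)[keep]),
             df = an[["Df"]][keep],
             f_statistic = an[["F value"]][keep],
             p_value = an[["Pr(>F)"]][keep],
             stringsAsFactors = FALSE)
}
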