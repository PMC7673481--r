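#' LUMA percent global methylation
#'
#' Computes percent methylation from luminometric methylation assay
#' peak ratios as `100 * (1 - (HpaII/EcoRI) / (MspI/EcoRI))`: HpaII
#' cuts only unmethylated CCGG while its isoschizomer MspI cuts
#' regardless, and EcoRI normalises for DNA input. Results outside
#' \[0, 100\] are clipped with a warning.
#'
#' @param hpaii_ecori HpaII/EcoRI peak ratio(s), positive.
#' @param mspi_ecori MspI/EcoRI peak ratio(s), positive.
#' @return Percent methylation, same length as the inputs.
#' @export
luma_percent <- function(hpaii_ecori, mspi_ecori) {
  if (any(mspi_ecori <= 0)) abort("MspI/EcoRI ratio must be positive")
  if (any(hpaii_ecori < 0)) abort("HpaII/EcoRI ratio cannot be negative")
  pct <- 100 * (1 - hpaii_ecori / mspi_ecori)
  if (any(pct < 0 | pct > 100)) {
    warn("LUMA percent outside [0, 100]; clipping")
    pct <- pmin(pmax(pct, 0), 100)
  }
  pct
}

#' Per-sample LUMA methylation from a measurement table
#'
#' Averages duplicate digestions per sample before applying the LUMA
#' formula, as the assay is run in duplicate for both HpaII and MspI.
#'
#' @param luma A tibble with sample_id, hpaii_ecori, mspi_ecori (one
#'   row per digestion replicate) and optional metadata columns (diet,
#'   tissue, sex), constant within sample.
#' @return One row per sample with `percent_meth` added.
#' @export
luma_summarize <- function(luma) {
  meta <- intersect(c("diet", "tissue", "sex"), names(luma))
  luma %>%
    group_by(across(all_of(c("sample_id", meta)))) %>%
    summarise(hpaii_ecori = mean(.data$hpaii_ecori),
              mspi_ecori = mean(.data$mspi_ecori), .groups = "drop") %>%
    mutate(percent_meth = luma_percent(.data$hpaii_ecori,
                                       .data$mspi_ecori))
}

#' Summarise pyrosequencing percent methylation per sample and gene
#'
#' Means over the assayed CpGs of each imprinted-gene germline DMR
#' amplicon (e.g. H19, Snrpn, Kcnq1ot1, Peg1, Peg3).
#'
#' @param pyro Long tibble: sample_id, gene, percent (one row per
#'   assayed CpG), plus optional metadata columns (diet, tissue, sex).
#' @return One row per sample x gene with `mean_percent` and the number
#'   of CpGs averaged.
#' @export
pyro_summarize <- function(pyro) {
  if (any(pyro$percent < 0 | pyro$percent > 100)) {
    abort("percent methylation must be within [0, 100]")
  }
  meta <- intersect(c("diet", "tissue", "sex"), names(pyro))
  pyro %>%
    group_by(across(all_of(c("sample_id", "gene", meta)))) %>%
    summarise(mean_percent = mean(.data$percent), n_cpgs = n(),
              .groups = "drop")
}

#' One-way ANOVA across diet groups
#'
#' Classical one-way ANOVA of a per-sample measurement on group labels.
#' When every group has zero within-group variance and all group means
#' are equal the test is degenerate and reported as F = 0, p = 1.
#'
#' @param data A tibble of per-sample measurements.
#' @param value,group Column names (strings) of the measurement and the
#'   group label.
#' @return A one-row tibble: statistic (F), df, df_resid, p_value.
#' @export
group_anova <- function(data, value = "value", group = "diet") {
  v <- data[[value]]
  g <- factor(data[[group]], levels = unique(data[[group]]))
  if (nlevels(g) < 2 || min(table(g)) < 2) {
    abort("need at least two groups with at least two samples each")
  }
  df1 <- nlevels(g) - 1L
  df2 <- length(v) - nlevels(g)
  if (sd(v) == 0) {
    # no variance anywhere: no effect by convention
    return(tibble(statistic = 0, df = df1, df_resid = df2, p_value = 1))
  }
  within_sd <- tapply(v, g, sd)
  if (all(within_sd == 0)) {
    # groups are distinct constants: infinitely strong separation
    return(tibble(statistic = Inf, df = df1, df_resid = df2, p_value = 0))
  }
  tab <- anova(aov(v ~ g))
  tibble(statistic = tab$`F value`[1], df = tab$Df[1],
         df_resid = tab$Df[2], p_value = tab$`Pr(>F)`[1])
}

#' Two-sample t-test for sex differences
#'
#' Two-tailed t-test of a measurement between males and females;
#' Welch's unequal-variance form by default.
#'
#' @param data A tibble of per-sample measurements.
#' @param value,sex Column names (strings) of the measurement and the
#'   sex label (levels among `"M"`, `"F"`).
#' @param var_equal Use the pooled-variance (Student) form.
#' @return A one-row tibble: statistic (t), df, p_value, mean_M,
#'   mean_F.
#' @export
sex_ttest <- function(data, value = "value", sex = "sex",
                      var_equal = FALSE) {
  v <- data[[value]]
  s <- data[[sex]]
  if (!all(c("M", "F") %in% s)) abort("both sexes must be present")
  m <- v[s == "M"]; f <- v[s == "F"]
  if (sd(c(m, f)) == 0) {
    return(tibble(statistic = 0, df = length(v) - 2, p_value = 1,
                  mean_M = mean(m), mean_F = mean(f)))
  }
  tt <- t.test(m, f, var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_M = mean(m), mean_F = mean(f))
}

#' Group comparison with sex-pooling rule
#'
#' Mirrors the analysis convention for targeted assays: first test for
#' a sex difference; if it is non-significant at `alpha`, pool the
#' sexes and run a single one-way ANOVA across diet groups, otherwise
#' analyse each sex separately.
#'
#' @param data Per-sample tibble with measurement, diet and sex
#'   columns.
#' @param value,group,sex Column names (strings).
#' @param alpha Significance level of the sex t-test used to decide
#'   pooling.
#' @return A tibble with one ANOVA row per analysis stratum (`"pooled"`
#'   or one per sex), plus the sex-test p-value.
#' @export
compare_assay_groups <- function(data, value = "value", group = "diet",
                                 sex = "sex", alpha = 0.05) {
  st <- sex_ttest(data, value, sex)
  if (st$p_value >= alpha) {
    out <- group_anova(data, value, group) %>% mutate(stratum = "pooled")
  } else {
    out <- purrr::map_dfr(c("M", "F"), function(s1) {
      group_anova(filter(data, .data[[sex]] == s1), value, group) %>%
        mutate(stratum = s1)
    })
  }
  out %>% mutate(sex_test_p = st$p_value) %>%
    select("stratum", "statistic", "df", "df_resid", "p_value",
           "sex_test_p")
}
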