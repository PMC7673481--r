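#' Derive litter-level reproductive outcomes
#'
#' Adds pre-implantation loss (corpora lutea minus implantation sites,
#' floored at zero with a warning since a miscount can make it
#' negative; missing corpora lutea give `NA`), post-implantation loss
#' and the number of viable embryos to a litter table. Implantation
#' counts exceeding corpora lutea raise a warning, not an error
#' (biologically possible miscount); resorptions exceeding
#' implantations are an error.
#'
#' @param litters Tibble with dam_id, diet, corpora_lutea,
#'   implantation_sites, resorptions.
#' @param postimplantation `"resorptions"` (default) counts resorption
#'   sites as the post-implantation losses; `"literal"` returns
#'   implantation sites minus resorptions (which equals the viable
#'   count) as sometimes printed.
#' @return `litters` with preimp_loss, postimp_loss and viable columns.
#' @export
litter_outcomes <- function(litters,
                            postimplantation = c("resorptions", "literal")) {
  postimplantation <- match.arg(postimplantation)
  if (any(litters$resorptions > litters$implantation_sites, na.rm = TRUE)) {
    abort("resorptions cannot exceed implantation sites")
  }
  raw_pre <- litters$corpora_lutea - litters$implantation_sites
  if (any(raw_pre < 0, na.rm = TRUE)) {
    warn("implantation sites exceed corpora lutea for some dams (likely CL miscount); pre-implantation loss floored at 0")
  }
  litters %>%
    mutate(preimp_loss = pmax(.data$corpora_lutea -
                                .data$implantation_sites, 0L),
           viable = .data$implantation_sites - .data$resorptions,
           postimp_loss = if (postimplantation == "resorptions") {
             .data$resorptions
           } else {
             .data$implantation_sites - .data$resorptions
           })
}

#' Classify embryo growth against control litters
#'
#' Computes each control litter's mean embryo weight, then the mean and
#' SD of those litter means; an embryo is growth `restricted` when its
#' weight is strictly below mean - `sd_mult` * SD, `enhanced` when
#' strictly above mean + `sd_mult` * SD, and `normal` otherwise
#' (boundary values are normal).
#'
#' @param embryos Tibble with dam_id and weight (grams).
#' @param litters Tibble with dam_id and diet (to locate control
#'   litters).
#' @param control Control diet label.
#' @param sd_mult Number of SDs defining the thresholds.
#' @return `embryos` with a `growth_class` factor
#'   (normal/restricted/enhanced); attributes `mu`, `sigma` and the
#'   thresholds.
#' @export
classify_growth <- function(embryos, litters, control = "Ctrl",
                            sd_mult = 2) {
  ctrl_dams <- litters$dam_id[litters$diet == control]
  litter_means <- embryos %>%
    filter(.data$dam_id %in% ctrl_dams) %>%
    group_by(.data$dam_id) %>%
    summarise(mw = mean(.data$weight), .groups = "drop")
  if (nrow(litter_means) < 2) {
    abort("need at least two control litters with embryos to estimate the SD")
  }
  mu <- mean(litter_means$mw)
  sigma <- sd(litter_means$mw)
  lo <- mu - sd_mult * sigma
  hi <- mu + sd_mult * sigma
  out <- embryos %>%
    mutate(growth_class = factor(case_when(
      .data$weight < lo ~ "restricted",
      .data$weight > hi ~ "enhanced",
      TRUE ~ "normal"), c("normal", "restricted", "enhanced")))
  structure(out, mu = mu, sigma = sigma, lower = lo, upper = hi)
}

#' Count abnormal outcomes per litter
#'
#' An abnormal outcome is a resorption, a growth-restricted embryo or a
#' growth-enhanced embryo; counts are additive per litter. A litter is
#' flagged when it has more than one abnormal outcome.
#'
#' @param litters Litter tibble (dam_id, diet, resorptions).
#' @param classified_embryos Output of [classify_growth()].
#' @return `litters` with `n_abnormal` and logical `flagged` columns.
#' @export
count_abnormal <- function(litters, classified_embryos) {
  growth_counts <- classified_embryos %>%
    group_by(.data$dam_id) %>%
    summarise(n_growth = sum(.data$growth_class != "normal"),
              .groups = "drop")
  litters %>%
    left_join(growth_counts, by = "dam_id") %>%
    mutate(n_growth = tidyr::replace_na(.data$n_growth, 0L),
           n_abnormal = .data$resorptions + .data$n_growth,
           flagged = .data$n_abnormal > 1) %>%
    select(-"n_growth")
}

#' Fisher's exact test of abnormal-litter proportions
#'
#' Builds the 2x2 table of flagged versus non-flagged litters in the
#' control group against the (pooled, by default) treated groups and
#' applies Fisher's exact test. The two-sided p-value sums all
#' hypergeometric tables at most as probable as the observed one;
#' `alternative = "greater"` tests for more flagged litters among the
#' treated groups, which is how a one-tailed trend in treated litters
#' is scored.
#'
#' @param flags Tibble with diet and logical `flagged` (from
#'   [count_abnormal()]).
#' @param control Control diet label.
#' @param pool_treated Pool all non-control diets into one row
#'   (default); otherwise each treated diet is tested against control
#'   separately.
#' @param alternative `"two.sided"` (default), `"greater"` or
#'   `"less"`, for the treated group relative to control.
#' @return A tibble with one row per comparison: group, flagged /
#'   total counts in both arms, odds_ratio (conditional MLE) and
#'   p_value.
#' @export
abnormal_litter_test <- function(flags, control = "Ctrl",
                                 pool_treated = TRUE,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  ctrl <- filter(flags, .data$diet == control)
  trt <- filter(flags, .data$diet != control)
  if (nrow(ctrl) == 0 || nrow(trt) == 0) {
    abort("both the control and at least one treated group must have litters")
  }
  one_test <- function(trt_sub, label) {
    m <- matrix(c(sum(trt_sub$flagged), sum(!trt_sub$flagged),
                  sum(ctrl$flagged), sum(!ctrl$flagged)),
                2, byrow = TRUE,
                dimnames = list(c("treated", "control"),
                                c("flagged", "not_flagged")))
    ft <- fisher.test(m, alternative = alternative)
    tibble(group = label,
           treated_flagged = m[1, 1], treated_total = sum(m[1, ]),
           control_flagged = m[2, 1], control_total = sum(m[2, ]),
           odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  }
  if (pool_treated) {
    one_test(trt, "pooled")
  } else {
    purrr::map_dfr(split(trt, trt$diet), ~ one_test(.x, .x$diet[1]))
  }
}

#' Dunnett many-to-one comparisons against the control diet
#'
#' One-way ANOVA of a per-litter outcome followed by Dunnett's
#' multiple-comparison test of every treated diet against control
#' (single-step adjustment over the joint multivariate-t distribution
#' of the contrast statistics). Adjusted p-values are never smaller
#' than the unadjusted ones.
#'
#' @param data Per-litter tibble.
#' @param value,group Column names (strings) of the outcome and the
#'   diet label.
#' @param control Control diet label.
#' @return A tibble with one row per treated diet: estimate (difference
#'   from control), se, statistic, p_value (Dunnett-adjusted).
#' @export
dunnett_vs_control <- function(data, value = "value", group = "diet",
                               control = "Ctrl") {
  g <- factor(data[[group]], levels = unique(data[[group]]))
  if (!control %in% levels(g)) abort("control level absent from data")
  if (min(table(g)) < 2) abort("every group needs at least two observations")
  g <- stats::relevel(g, control)
  df <- tibble(y = data[[value]], g = g)
  if (sd(df$y) == 0) {
    lev <- levels(g)[-1]
    return(tibble(group = lev, estimate = 0, se = 0, statistic = 0,
                  p_value = 1))
  }
  fit <- aov(y ~ g, data = df)
  # single-step adjustment integrates a multivariate t; seed fixed for
  # a reproducible quasi-Monte-Carlo result
  gl <- withr::with_seed(1L,
    summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))))
  tibble(group = levels(g)[-1],
         estimate = unname(gl$test$coefficients),
         se = unname(gl$test$sigma),
         statistic = unname(gl$test$tstat),
         p_value = unname(gl$test$pvalues))
}
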