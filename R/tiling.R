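#' Aggregate per-CpG counts into 100-bp tiles
#'
#' Assigns every CpG to the step-wise tiling window containing it
#' (0-based half-open tiles; `tile_size` must be a multiple of `step`,
#' and with `step < tile_size` windows overlap and a CpG contributes to
#' each window covering it). Per sample and tile this records the number
#' of covered CpGs, the summed read coverage, summed methylated counts,
#' the minimum per-CpG coverage, and the tile methylation level as the
#' unweighted mean of per-CpG methylation fractions (in percent).
#'
#' @param methylomes Long per-CpG tibble (see [read_coverage_file()]),
#'   any number of samples.
#' @param tile_size Window width in bp.
#' @param step Window step in bp.
#' @return A per-sample, per-tile tibble: sample metadata, chrom, start,
#'   end, n_cpgs, coverage, count_meth, cov_min_cpg, meth (percent).
#' @export
aggregate_tiles <- function(methylomes, tile_size = 100, step = 100) {
  cols <- c("sample_id", "tissue", "diet", "sex", "chrom", "start", "end",
            "n_cpgs", "coverage", "count_meth", "cov_min_cpg", "meth")
  if (nrow(methylomes) == 0) {
    return(tibble(sample_id = character(), tissue = character(),
                  diet = character(), sex = character(), chrom = character(),
                  start = integer(), end = integer(), n_cpgs = integer(),
                  coverage = integer(), count_meth = integer(),
                  cov_min_cpg = integer(), meth = double()))
  }
  if (tile_size %% step != 0) abort("tile_size must be a multiple of step")
  unsorted <- methylomes %>%
    group_by(.data$sample_id, .data$chrom) %>%
    summarise(u = is.unsorted(.data$pos), .groups = "drop") %>%
    pull(.data$u) %>% any()
  if (unsorted) {
    warn("per-CpG input was not sorted by position; sorting internally")
    methylomes <- arrange(methylomes, .data$sample_id, .data$chrom,
                          .data$pos)
  }
  phases <- seq(0L, tile_size - step, by = step)
  purrr::map_dfr(phases, function(ph) {
    methylomes %>%
      mutate(start = as.integer(
        ((.data$pos - 1L - ph) %/% tile_size) * tile_size + ph)) %>%
      filter(.data$start >= 0L)
  }) %>%
    mutate(end = .data$start + as.integer(tile_size),
           cov = .data$count_meth + .data$count_unmeth,
           frac = .data$count_meth / .data$cov) %>%
    group_by(.data$sample_id, .data$tissue, .data$diet, .data$sex,
             .data$chrom, .data$start, .data$end) %>%
    summarise(n_cpgs = n(), coverage = sum(.data$cov),
              count_meth = sum(.data$count_meth),
              cov_min_cpg = min(.data$cov),
              meth = 100 * mean(.data$frac), .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$sample_id) %>%
    select(all_of(cols))
}

# closed-form likelihood-ratio test of a binomial logistic model with a
# single two-level group covariate: the MLE fits each group's pooled
# proportion, so the deviance difference depends only on pooled counts
lrt_pooled <- function(Mc, Cc, Mt, Ct) {
  ll <- function(M, C) {
    p <- M / C
    ifelse(M > 0, M * log(p), 0) + ifelse(C > M, (C - M) * log(1 - p), 0)
  }
  G <- 2 * (ll(Mc, Cc) + ll(Mt, Ct) - ll(Mc + Mt, Cc + Ct))
  pmax(G, 0)
}

#' Test tiles for differential methylation between two diet groups
#'
#' Restricts to tiles testable in every sample of the contrast (at least
#' `min_cpgs` CpGs and tile coverage of at least `min_coverage` in each
#' sample; with `coverage_mode = "cpg"`, every single CpG must reach
#' `min_coverage` instead) and computes a per-tile p-value: a
#' likelihood-ratio test of a binomial logistic regression of
#' (methylated, unmethylated) counts on group when both groups have two
#' or more samples, or Fisher's exact test on pooled counts when either
#' group has exactly one sample. The group difference `delta`
#' (treatment minus control, percentage points) is computed from
#' coverage-weighted pooled counts; the unweighted means of per-sample
#' tile methylation are reported alongside. q-values are
#' Benjamini-Hochberg across all testable tiles.
#'
#' @param tiles Output of [aggregate_tiles()].
#' @param treatment,control Diet labels to contrast.
#' @param min_cpgs Minimum CpGs per tile per sample.
#' @param min_coverage Minimum coverage per sample (per tile, or per CpG
#'   with `coverage_mode = "cpg"`).
#' @param coverage_mode `"tile"` (summed CpG coverage, default) or
#'   `"cpg"` (stricter, every CpG).
#' @param overdispersion If `TRUE`, scale the likelihood-ratio statistic
#'   by a per-tile Pearson dispersion factor estimated across samples
#'   (floored at 1) before computing the p-value. Off by default.
#' @return A tibble of class `tile_dm` with chrom, start, end, n_cpgs,
#'   per-group pooled coverage and methylation (percent), unweighted
#'   mean methylation, delta, p_value, q_value. Attributes record the
#'   contrast, tissue(s), group sizes and thresholds.
#' @export
test_tiles <- function(tiles, treatment, control = "Ctrl", min_cpgs = 2,
                       min_coverage = 10, coverage_mode = c("tile", "cpg"),
                       overdispersion = FALSE) {
  coverage_mode <- match.arg(coverage_mode)
  sub <- filter(tiles, .data$diet %in% c(control, treatment))
  samp <- distinct(sub, .data$sample_id, .data$diet)
  n_ctrl <- sum(samp$diet == control)
  n_treat <- sum(samp$diet == treatment)
  if (n_ctrl < 1 || n_treat < 1) {
    abort("both contrast groups need at least one sample")
  }
  covcol <- if (coverage_mode == "tile") "coverage" else "cov_min_cpg"
  testable <- sub %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    filter(n() == n_ctrl + n_treat,
           all(.data$n_cpgs >= min_cpgs),
           all(.data[[covcol]] >= min_coverage)) %>%
    ungroup()

  res <- testable %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(
      n_cpgs = max(.data$n_cpgs),
      cov_ctrl = sum(.data$coverage[.data$diet == control]),
      m_ctrl = sum(.data$count_meth[.data$diet == control]),
      cov_treat = sum(.data$coverage[.data$diet == treatment]),
      m_treat = sum(.data$count_meth[.data$diet == treatment]),
      mean_meth_ctrl = mean(.data$meth[.data$diet == control]),
      mean_meth_treat = mean(.data$meth[.data$diet == treatment]),
      phi = if (overdispersion) {
        p0 <- sum(.data$count_meth) / sum(.data$coverage)
        if (p0 <= 0 || p0 >= 1 || n() <= 2) 1 else
          max(1, sum((.data$count_meth - .data$coverage * p0)^2 /
                       (.data$coverage * p0 * (1 - p0))) / (n() - 2))
      } else 1,
      .groups = "drop") %>%
    mutate(meth_ctrl = 100 * .data$m_ctrl / .data$cov_ctrl,
           meth_treat = 100 * .data$m_treat / .data$cov_treat,
           delta = .data$meth_treat - .data$meth_ctrl)

  if (nrow(res) > 0 && n_ctrl >= 2 && n_treat >= 2) {
    G <- lrt_pooled(res$m_ctrl, res$cov_ctrl, res$m_treat, res$cov_treat)
    res$p_value <- pchisq(G / res$phi, df = 1, lower.tail = FALSE)
  } else if (nrow(res) > 0) {
    res$p_value <- purrr::pmap_dbl(
      list(res$m_ctrl, res$cov_ctrl, res$m_treat, res$cov_treat),
      function(mc, cc, mt, ct) {
        p <- fisher.test(matrix(c(mc, cc - mc, mt, ct - mt), 2,
                                byrow = TRUE))$p.value
        min(max(p, 0), 1)  # guard tiny floating-point overshoot
      })
  } else res$p_value <- double()
  res$q_value <- adjust_fdr(res$p_value)
  res <- res %>%
    select("chrom", "start", "end", "n_cpgs", "cov_ctrl", "cov_treat",
           "meth_ctrl", "meth_treat", "mean_meth_ctrl", "mean_meth_treat",
           "delta", "p_value", "q_value")
  structure(res, class = c("tile_dm", class(res)),
            control = control, treatment = treatment,
            tissue = unique(sub$tissue),
            n_ctrl = n_ctrl, n_treat = n_treat,
            min_cpgs = min_cpgs, min_coverage = min_coverage,
            coverage_mode = coverage_mode)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; `NA` p-values are excluded
#' from the number of tests and returned as `NA`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Call differentially methylated tiles (DMTs)
#'
#' A tile is a DMT when its q-value is strictly below `q_threshold` and
#' its absolute methylation difference strictly exceeds `min_delta`
#' percentage points. Each DMT carries its direction (hyper = gain in
#' treatment) and a magnitude bin with boundaries at 15 and 20
#' percentage points.
#'
#' @param results A `tile_dm` tibble from [test_tiles()].
#' @param q_threshold q-value cutoff (exclusive).
#' @param min_delta Minimum absolute delta in percentage points
#'   (exclusive).
#' @return The DMT subset with `direction` and `magnitude_bin` columns,
#'   class `dmt_tbl`; attributes carry the contrast and the number of
#'   tiles tested.
#' @export
call_dmts <- function(results, q_threshold = 0.01, min_delta = 10) {
  out <- results %>%
    as_tibble() %>%
    filter(!is.na(.data$q_value), .data$q_value < q_threshold,
           abs(.data$delta) > min_delta) %>%
    mutate(direction = factor(if_else(.data$delta > 0, "hyper", "hypo"),
                              c("hyper", "hypo")),
           magnitude_bin = cut(abs(.data$delta),
                               breaks = c(-Inf, 15, 20, Inf),
                               labels = c("10-15", "15-20", ">20"),
                               right = TRUE))
  structure(out, class = c("dmt_tbl", class(out)),
            control = attr(results, "control"),
            treatment = attr(results, "treatment"),
            tissue = attr(results, "tissue"),
            n_tested = nrow(results),
            q_threshold = q_threshold, min_delta = min_delta)
}

#' Summarise a DMT set by direction and magnitude
#'
#' @param dmts A DMT tibble from [call_dmts()].
#' @return A tibble of class `dmt_summary` with one row per magnitude
#'   bin (counts of hyper, hypo and all DMTs) and attributes `n`,
#'   `hyper_fraction`, `hypo_fraction` (fractions absent when the set is
#'   empty).
#' @export
summarize_dmts <- function(dmts) {
  bins <- c("10-15", "15-20", ">20")
  tab <- dmts %>%
    as_tibble() %>%
    count(.data$magnitude_bin, .data$direction) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("hyper", "hypo")) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }
  out <- tibble(magnitude_bin = factor(bins, bins)) %>%
    left_join(tab, by = "magnitude_bin") %>%
    mutate(across(c("hyper", "hypo"), ~ tidyr::replace_na(.x, 0L)),
           total = .data$hyper + .data$hypo)
  n <- sum(out$total)
  structure(out, class = c("dmt_summary", class(out)), n = n,
            hyper_fraction = if (n > 0) sum(out$hyper) / n else NULL,
            hypo_fraction = if (n > 0) sum(out$hypo) / n else NULL,
            treatment = attr(dmts, "treatment"),
            tissue = attr(dmts, "tissue"))
}
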