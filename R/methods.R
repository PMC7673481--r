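#' @method tidy tile_dm
#' @export
tidy.tile_dm <- function(x, ...) as_tibble(x)

#' @method glance tile_dm
#' @export
glance.tile_dm <- function(x, ...) {
  tibble(control = attr(x, "control"), treatment = attr(x, "treatment"),
         n_ctrl = attr(x, "n_ctrl"), n_treat = attr(x, "n_treat"),
         n_tiles_tested = nrow(x),
         n_q_below_0.01 = sum(x$q_value < 0.01, na.rm = TRUE),
         median_abs_delta = stats::median(abs(x$delta)))
}

#' @method tidy dmt_tbl
#' @export
tidy.dmt_tbl <- function(x, ...) as_tibble(x)

#' @method glance dmt_tbl
#' @export
glance.dmt_tbl <- function(x, ...) {
  n <- nrow(x)
  tibble(treatment = attr(x, "treatment"),
         n_tested = attr(x, "n_tested"), n_dmts = n,
         hyper_fraction = if (n > 0) mean(x$direction == "hyper") else
           NA_real_,
         q_threshold = attr(x, "q_threshold"),
         min_delta = attr(x, "min_delta"))
}

#' @method tidy dmt_summary
#' @export
tidy.dmt_summary <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("hyper", "hypo"), names_to = "direction",
                        values_to = "n")
}

#' @method glance dmt_summary
#' @export
glance.dmt_summary <- function(x, ...) {
  tibble(n_dmts = attr(x, "n"),
         hyper_fraction = attr(x, "hyper_fraction") %||% NA_real_,
         hypo_fraction = attr(x, "hypo_fraction") %||% NA_real_)
}

#' @method tidy maternal_overlap
#' @export
tidy.maternal_overlap <- function(x, ...) {
  as_tibble(x) %>%
    filter(.data$dynamic_class != "Total") %>%
    tidyr::pivot_longer(c("hyper", "hypo"), names_to = "direction",
                        values_to = "n")
}

#' @method glance maternal_overlap
#' @export
glance.maternal_overlap <- function(x, ...) {
  tibble(n_dmts_at_maternal_regions = attr(x, "n"),
         gvo_high_fraction = attr(x, "gvo_high_fraction"))
}

#' @method glance conserved_dmt
#' @export
glance.conserved_dmt <- function(x, ...) {
  cts <- attr(x, "counts")
  tibble(total = cts$total, concordant = cts$concordant,
         high_magnitude_concordant = cts$high_magnitude_concordant)
}

#' Volcano plot of tile-level differential methylation
#'
#' @param object A `tile_dm` result from [test_tiles()].
#' @param q_threshold,min_delta DMT thresholds drawn as guide lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tile_dm
#' @export
autoplot.tile_dm <- function(object, q_threshold = 0.01, min_delta = 10,
                             ...) {
  df <- as_tibble(object) %>%
    mutate(is_dmt = .data$q_value < q_threshold &
             abs(.data$delta) > min_delta)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta,
                                   -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$is_dmt)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-min_delta, min_delta),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "methylation difference (percentage points)",
                  y = expression(-log[10] ~ q),
                  title = paste(attr(object, "treatment"), "vs",
                                attr(object, "control"))) +
    ggplot2::theme_minimal()
}

#' Bar chart of DMT counts by magnitude bin and direction
#'
#' @param object A `dmt_summary` from [summarize_dmts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmt_summary
#' @export
autoplot.dmt_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$magnitude_bin, .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "|delta| bin (percentage points)", y = "DMTs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Litter outcome plot by diet group
#'
#' Jittered per-litter points with group means for a chosen outcome.
#'
#' @param litters A litter tibble (e.g. from [litter_outcomes()]).
#' @param outcome Column name (string) to plot.
#' @return A ggplot object.
#' @export
plot_litter_outcome <- function(litters, outcome = "viable") {
  diets <- intersect(.diets, unique(litters$diet))
  df <- mutate(litters, diet = factor(.data$diet, diets))
  ggplot2::ggplot(df, ggplot2::aes(.data$diet, .data[[outcome]])) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
}

#' @export
print.maternal_overlap <- function(x, ...) {
  cat("DMTs at maternally inherited regions (GVO->ICM dynamics)\n")
  NextMethod()
  cat(sprintf("GVO >= 75%% fraction: %s\n",
              format(attr(x, "gvo_high_fraction"), digits = 3)))
  invisible(x)
}
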