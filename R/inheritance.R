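#' Select regions that inherit methylation from the maternal allele
#'
#' Matches the sperm, germinal-vesicle oocyte (GVO) and maternal-allele
#' inner-cell-mass (ICMm) 100-bp tracks by coordinates (regions missing
#' from any track are dropped) and keeps regions where sperm methylation
#' is at most `sperm_max` and both GVO and ICMm methylation are at least
#' `gvo_icm_min` (set `require_both = FALSE` for either-track
#' semantics). Each retained region is classed by its GVO-to-ICM
#' dynamics: `gain` when ICMm - GVO >= `dynamic_delta`, `loss` when
#' GVO - ICMm >= `dynamic_delta`, otherwise `stable`; `gvo_high` flags
#' GVO methylation at or above `gvo_high_cutoff`.
#'
#' @param sperm,gvo,icm Tibbles chrom, start, end, meth on the same
#'   100-bp grid (see [read_reference_track()]).
#' @param sperm_max Maximum sperm methylation, percent (inclusive).
#' @param gvo_icm_min Minimum GVO/ICMm methylation, percent (inclusive).
#' @param dynamic_delta Gain/loss boundary in percentage points
#'   (inclusive).
#' @param gvo_high_cutoff GVO-high flag cutoff, percent (inclusive).
#' @param require_both If `TRUE` (default) both GVO and ICMm must pass
#'   `gvo_icm_min`; if `FALSE`, either suffices.
#' @return A tibble chrom, start, end, sperm_meth, gvo_meth, icm_meth,
#'   dynamic_class (factor gain/stable/loss), gvo_high.
#' @export
select_maternal_regions <- function(sperm, gvo, icm, sperm_max = 10,
                                    gvo_icm_min = 25, dynamic_delta = 10,
                                    gvo_high_cutoff = 75,
                                    require_both = TRUE) {
  check_grid <- function(x, nm) {
    if (!all(c("chrom", "start", "end", "meth") %in% names(x))) {
      abort(paste0(nm, " track needs columns chrom, start, end, meth"))
    }
    w <- unique(x$end - x$start)
    if (length(w) != 1 || any(x$start %% w != 0)) {
      abort(paste0(nm, " track is not on a uniform 100-bp style grid"))
    }
    w
  }
  ws <- c(check_grid(sperm, "sperm"), check_grid(gvo, "GVO"),
          check_grid(icm, "ICMm"))
  if (length(unique(ws)) != 1) abort("reference tracks are on different grids")

  merged <- sperm %>% rename(sperm_meth = "meth") %>%
    inner_join(rename(gvo, gvo_meth = "meth"),
               by = c("chrom", "start", "end")) %>%
    inner_join(rename(icm, icm_meth = "meth"),
               by = c("chrom", "start", "end"))
  pass_gvo_icm <- if (require_both) {
    merged$gvo_meth >= gvo_icm_min & merged$icm_meth >= gvo_icm_min
  } else {
    merged$gvo_meth >= gvo_icm_min | merged$icm_meth >= gvo_icm_min
  }
  merged %>%
    filter(.data$sperm_meth <= sperm_max, pass_gvo_icm) %>%
    mutate(dynamic_class = factor(case_when(
      .data$icm_meth - .data$gvo_meth >= dynamic_delta ~ "gain",
      .data$gvo_meth - .data$icm_meth >= dynamic_delta ~ "loss",
      TRUE ~ "stable"), c("gain", "stable", "loss")),
      gvo_high = .data$gvo_meth >= gvo_high_cutoff) %>%
    arrange(.data$chrom, .data$start)
}

#' Cross-tabulate DMTs against maternally inherited regions
#'
#' Intersects a DMT set with the maternal-region set by exact tile
#' coordinates and counts DMTs by GVO-to-ICM dynamic class (gain /
#' stable / loss) and direction (hyper / hypo), with row and grand
#' totals, in the layout of a germline-inheritance classification
#' table. Also reports the fraction of intersected DMTs at regions with
#' GVO methylation >= 75 percent.
#'
#' @param maternal Output of [select_maternal_regions()].
#' @param dmts A DMT tibble from [call_dmts()].
#' @return A tibble of class `maternal_overlap`: one row per dynamic
#'   class plus a `Total` row, columns hyper, hypo, all_dmts.
#'   Attributes: `n` (grand total), `gvo_high_fraction`, and the joined
#'   per-DMT detail in `detail`.
#' @export
intersect_with_dmts <- function(maternal, dmts) {
  detail <- inner_join(
    as_tibble(maternal),
    as_tibble(dmts) %>% select("chrom", "start", "end", "delta",
                               "direction"),
    by = c("chrom", "start", "end"))
  counts <- detail %>%
    count(.data$dynamic_class, .data$direction, .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) %>%
    mutate(all_dmts = .data$hyper + .data$hypo)
  total <- tibble(dynamic_class = "Total",
                  hyper = sum(counts$hyper), hypo = sum(counts$hypo),
                  all_dmts = sum(counts$all_dmts))
  out <- bind_rows(mutate(counts,
                          dynamic_class = as.character(.data$dynamic_class)),
                   total)
  structure(out, class = c("maternal_overlap", class(out)),
            n = total$all_dmts,
            gvo_high_fraction = if (nrow(detail) > 0)
              mean(detail$gvo_high) else NA_real_,
            detail = detail,
            treatment = attr(dmts, "treatment"),
            tissue = attr(dmts, "tissue"))
}
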