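#' Assign genomic feature categories to tiles
#'
#' Each tile gets exactly one of promoter / exon / intron / intergenic.
#' Overlap is resolved by fixed precedence (promoter > exon > intron),
#' i.e. a tile touching both an exon and an intron is exonic regardless
#' of overlap widths; within the winning feature class the gene with
#' the largest overlap supplies `gene_id`. Tiles overlapping nothing
#' (including tiles on chromosomes absent from the gene model, with a
#' warning) are intergenic.
#'
#' @param tiles A tibble with chrom, start, end (0-based half-open);
#'   e.g. a `tile_dm` or DMT tibble.
#' @param gene_model A gene-model tibble from [read_gene_model()] or
#'   [sim_gene_model()].
#' @return `tiles` with `feature` (factor) and `gene_id` columns added.
#' @export
annotate_tiles <- function(tiles, gene_model) {
  tiles <- as_tibble(tiles)
  if (nrow(tiles) == 0) {
    return(mutate(tiles, feature = factor(character(), .features),
                  gene_id = character()))
  }
  missing_chrom <- setdiff(unique(tiles$chrom), unique(gene_model$chrom))
  if (length(missing_chrom) > 0) {
    warn(paste("chromosomes absent from gene model, tiles set intergenic:",
               paste(missing_chrom, collapse = ", ")))
  }
  q <- GenomicRanges::GRanges(tiles$chrom,
                              IRanges::IRanges(tiles$start + 1L, tiles$end))
  s <- GenomicRanges::GRanges(gene_model$chrom,
                              IRanges::IRanges(gene_model$start + 1L,
                                               gene_model$end))
  # seqlevel mismatches are expected (handled above); silence the
  # GenomicRanges notice about them
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  tiles$feature <- factor("intergenic", .features)
  tiles$gene_id <- NA_character_
  if (length(qh) > 0) {
    ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qh],
                                             IRanges::ranges(s)[sh]))
    hit_tbl <- tibble(tile = qh,
                      feature = gene_model$feature[sh],
                      gene_id = gene_model$gene_id[sh],
                      overlap = ov) %>%
      mutate(prec = match(.data$feature, .features)) %>%
      group_by(.data$tile) %>%
      filter(.data$prec == min(.data$prec)) %>%
      arrange(dplyr::desc(.data$overlap), .by_group = TRUE) %>%
      dplyr::slice(1) %>%
      ungroup()
    tiles$feature[hit_tbl$tile] <- factor(hit_tbl$feature, .features)
    tiles$gene_id[hit_tbl$tile] <- hit_tbl$gene_id
  }
  tiles
}

#' Test enrichment of a feature category in DMTs versus background
#'
#' Two-sided Fisher's exact test on the 2x2 table (category vs rest) x
#' (DMT vs background), with the sample odds ratio.
#'
#' @param dmt_features,background_features Annotated tibbles with a
#'   `feature` column (from [annotate_tiles()]), or named count vectors
#'   over categories.
#' @param category The category tested (default `"intergenic"`).
#' @return A one-row tibble: category, counts of the 2x2 table,
#'   odds_ratio (sample OR; `NA` when a margin is zero and the ratio is
#'   undefined), p_value.
#' @export
enrichment_test <- function(dmt_features, background_features,
                            category = "intergenic") {
  to_counts <- function(x) {
    if (is.data.frame(x)) {
      c(sum(x$feature == category), sum(x$feature != category))
    } else {
      inc <- names(x) == category
      c(sum(x[inc]), sum(x[!inc]))
    }
  }
  d <- to_counts(dmt_features)
  b <- to_counts(background_features)
  if (sum(d) == 0 || sum(b) == 0) abort("both count tables must be non-empty")
  m <- matrix(c(d, b), 2, byrow = TRUE,
              dimnames = list(c("dmt", "background"),
                              c(category, "other")))
  or <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    NA_real_
  } else (d[1] * b[2]) / (d[2] * b[1])
  tibble(category = category,
         dmt_in = d[1], dmt_out = d[2],
         background_in = b[1], background_out = b[2],
         odds_ratio = or,
         p_value = fisher.test(m)$p.value)
}

#' Intersect DMT sets from two tissues
#'
#' Tiles are matched by exact coordinates (both sets share the 100-bp
#' grid). For each shared tile, `concordant` records whether the
#' methylation change has the same sign in both tissues and
#' `high_magnitude` whether at least one tissue changes by more than
#' `high_cutoff` percentage points.
#'
#' @param dmts_a,dmts_b DMT tibbles from [call_dmts()] (e.g. placenta
#'   and cortex for the same diet contrast).
#' @param high_cutoff Percentage-point cutoff for the high-magnitude
#'   flag (exclusive).
#' @return A tibble of class `conserved_dmt` with chrom, start, end,
#'   delta_a, delta_b, concordant, high_magnitude; attribute `counts`
#'   holds total, concordant and high-magnitude-concordant counts.
#' @export
intersect_tissues <- function(dmts_a, dmts_b, high_cutoff = 20) {
  a <- as_tibble(dmts_a) %>% select("chrom", "start", "end",
                                    delta_a = "delta")
  b <- as_tibble(dmts_b) %>% select("chrom", "start", "end",
                                    delta_b = "delta")
  out <- inner_join(a, b, by = c("chrom", "start", "end")) %>%
    mutate(concordant = sign(.data$delta_a) == sign(.data$delta_b),
           high_magnitude = pmax(abs(.data$delta_a),
                                 abs(.data$delta_b)) > high_cutoff)
  structure(out, class = c("conserved_dmt", class(out)),
            counts = list(total = nrow(out),
                          concordant = sum(out$concordant),
                          high_magnitude_concordant =
                            sum(out$concordant & out$high_magnitude)))
}
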