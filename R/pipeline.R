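#' Configuration for an end-to-end pipeline run
#'
#' Collects every threshold of the analysis with its standard default:
#' 100-bp tiles, >= 2 CpGs per tile, >= 10x tile coverage per sample,
#' q < 0.01 and |delta| > 10 percentage points for DMT calling, sperm
#' <= 10 percent and GVO/ICMm >= 25 percent for maternal regions with a 10-point
#' gain/loss boundary, and the 2-SD growth classifier.
#'
#' @param output_dir Directory for all written outputs.
#' @param seed Integer seed passed to the simulator.
#' @param tile_size,step,min_cpgs,min_coverage,q_threshold,min_delta
#'   Tiling and DMT-calling thresholds.
#' @param sperm_max,gvo_icm_min,dynamic_delta Maternal-region
#'   thresholds (percent / percentage points).
#' @param growth_sd_mult SD multiplier of the growth classifier.
#' @param high_magnitude_cutoff Cross-tissue high-magnitude cutoff
#'   (percentage points).
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, tile_size = 100, step = 100,
                       min_cpgs = 2, min_coverage = 10, q_threshold = 0.01,
                       min_delta = 10, sperm_max = 10, gvo_icm_min = 25,
                       dynamic_delta = 10, growth_sd_mult = 2,
                       high_magnitude_cutoff = 20,
                       sim = sim_config(seed = seed)) {
  cfg <- as.list(environment())
  stopifnot(inherits(sim, "sim_config"))
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Simulates methylomes, reference tracks, a gene model and litter
#' records from the embedded [sim_config()], then runs every stage:
#' tile aggregation, per-diet DMT calling against control in each
#' tissue, DMT summaries, genomic annotation with an intergenic
#' enrichment test, cross-tissue intersection, maternal-inheritance
#' classification, and litter statistics (outcomes, growth classes,
#' abnormal-litter Fisher test, Dunnett comparisons). All tables are
#' written as TSV/BED under `output_dir` together with a JSON manifest
#' of thresholds, seed and stage-by-stage filter counts. Deterministic
#' under a fixed seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  log_counts <- list()

  sim <- sim_methylomes(cfg$sim)
  tracks <- sim_reference_tracks(cfg$sim)
  gene_model <- sim_gene_model(cfg$sim)
  lit <- sim_litters(cfg$sim)
  readr::write_tsv(sim$truth, out("truth_planted_dmts.tsv"))
  readr::write_tsv(gene_model, out("gene_model.tsv"))
  readr::write_tsv(lit$litters, out("litters.tsv"))
  readr::write_tsv(lit$embryos, out("embryos.tsv"))
  for (src in unique(tracks$tracks$source)) {
    readr::write_tsv(filter(tracks$tracks, .data$source == src) %>%
                       select(-"source"),
                     out(paste0("track_", src, ".tsv")))
  }

  tiles <- aggregate_tiles(sim$methylomes, cfg$tile_size, cfg$step)
  log_counts$n_cpgs <- nrow(distinct(sim$methylomes, .data$chrom, .data$pos))
  log_counts$n_tiles_covered <- nrow(distinct(tiles, .data$chrom,
                                              .data$start))

  diets <- cfg$sim$diets
  treated <- diets[-1]
  dmt_sets <- list()
  maternal <- select_maternal_regions(
    filter(tracks$tracks, .data$source == "sperm"),
    filter(tracks$tracks, .data$source == "GVO"),
    filter(tracks$tracks, .data$source == "ICMm"),
    sperm_max = cfg$sperm_max, gvo_icm_min = cfg$gvo_icm_min,
    dynamic_delta = cfg$dynamic_delta)
  readr::write_tsv(maternal, out("maternal_regions.tsv"))
  log_counts$n_maternal_regions <- nrow(maternal)

  for (ts in cfg$sim$tissues) {
    tiles_ts <- filter(tiles, .data$tissue == ts)
    for (tr in treated) {
      tag <- paste0(ts, "_", tr)
      res <- test_tiles(tiles_ts, treatment = tr, control = diets[1],
                        min_cpgs = cfg$min_cpgs,
                        min_coverage = cfg$min_coverage)
      dmts <- call_dmts(res, cfg$q_threshold, cfg$min_delta)
      dmt_sets[[tag]] <- dmts
      log_counts[[paste0("n_testable_", tag)]] <- nrow(res)
      log_counts[[paste0("n_dmts_", tag)]] <- nrow(dmts)
      write_dmt_bed(dmts, out(paste0("dmts_", tag, ".bed")))
      readr::write_tsv(as_tibble(summarize_dmts(dmts)),
                       out(paste0("dmt_summary_", tag, ".tsv")))

      annot_dmt <- annotate_tiles(dmts, gene_model)
      annot_bg <- annotate_tiles(distinct(res, .data$chrom, .data$start,
                                          .data$end), gene_model)
      readr::write_tsv(annot_dmt, out(paste0("dmts_annotated_", tag,
                                             ".tsv")))
      enr <- enrichment_test(annot_dmt, annot_bg, "intergenic")
      readr::write_tsv(enr, out(paste0("enrichment_intergenic_", tag,
                                       ".tsv")))
      mo <- intersect_with_dmts(maternal, dmts)
      readr::write_tsv(as_tibble(mo), out(paste0("maternal_overlap_", tag,
                                                 ".tsv")))
    }
  }

  for (tr in treated) {
    cons <- intersect_tissues(dmt_sets[[paste0(cfg$sim$tissues[1], "_", tr)]],
                              dmt_sets[[paste0(cfg$sim$tissues[2], "_", tr)]],
                              high_cutoff = cfg$high_magnitude_cutoff)
    readr::write_tsv(as_tibble(cons),
                     out(paste0("conserved_dmts_", tr, ".tsv")))
    log_counts[[paste0("n_conserved_", tr)]] <- attr(cons, "counts")$total
  }

  litters <- litter_outcomes(lit$litters)
  embryos <- classify_growth(lit$embryos, litters,
                             control = diets[1],
                             sd_mult = cfg$growth_sd_mult)
  flags <- count_abnormal(litters, embryos)
  fisher <- abnormal_litter_test(flags, control = diets[1])
  dunnett <- purrr::map_dfr(
    c("viable", "resorptions", "preimp_loss", "postimp_loss"),
    function(oc) mutate(dunnett_vs_control(litters, oc, "diet", diets[1]),
                        outcome = oc, .before = 1))
  readr::write_tsv(litters, out("litter_outcomes.tsv"))
  readr::write_tsv(embryos, out("embryos_classified.tsv"))
  readr::write_tsv(fisher, out("abnormal_litter_fisher.tsv"))
  readr::write_tsv(dunnett, out("litter_dunnett.tsv"))

  manifest <- list(
    package_version = as.character(packageVersion("foltile")),
    seed = cfg$seed,
    thresholds = cfg[c("tile_size", "step", "min_cpgs", "min_coverage",
                       "q_threshold", "min_delta", "sperm_max",
                       "gvo_icm_min", "dynamic_delta", "growth_sd_mult",
                       "high_magnitude_cutoff")],
    counts = log_counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(tiles = tiles, dmts = dmt_sets, maternal = maternal,
                 litters = litters, embryos = embryos, fisher = fisher,
                 dunnett = dunnett, manifest = manifest))
}
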