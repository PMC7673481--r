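#' Read a Bismark-style coverage file into a per-CpG count table
#'
#' Parses the six-column Bismark coverage dialect (chrom, start, end,
#' percent methylation, count methylated, count unmethylated; positions
#' 1-based inclusive) into a tidy per-CpG table. Records at the same
#' position are merged by summing counts, zero-coverage records are
#' dropped, and the result is sorted by (chrom, pos).
#'
#' @param path Path to a tab-separated coverage file.
#' @param sample_id Sample identifier attached to every record.
#' @param tissue,diet,sex Sample metadata; `diet` is one of
#'   `"Ctrl"`, `"7FD"`, `"10FS"`, `"20FS"` when supplied.
#' @return A tibble with columns `sample_id`, `tissue`, `diet`, `sex`,
#'   `chrom`, `pos` (1-based), `count_meth`, `count_unmeth`.
#' @export
read_coverage_file <- function(path, sample_id, tissue = NA_character_,
                               diet = NA_character_, sex = "unknown") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                        "percent", "count_meth",
                                        "count_unmeth"),
                    col_types = "cddddd", comment = "#",
                    progress = FALSE))
  prb <- readr::problems(raw)
  if (nrow(prb) > 0) {
    abort(sprintf("malformed coverage line %d in %s: expected %s, got '%s'",
                  prb$row[1], path, prb$expected[1], prb$actual[1]))
  }
  if (ncol(raw) != 6) abort("coverage file must have six tab-separated columns")
  bad <- which(raw$count_meth < 0 | raw$count_unmeth < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative count on line %d of %s", bad[1], path))
  }
  new_methylome(raw$chrom, raw$start, raw$count_meth, raw$count_unmeth,
                sample_id, tissue, diet, sex)
}

#' Read a methylKit-style raw file as a per-CpG count table
#'
#' Alternate input dialect: columns id, chr, base, strand, coverage,
#' freqC, freqT (frequencies in percent). Converted to methylated /
#' unmethylated counts.
#'
#' @inheritParams read_coverage_file
#' @return Same layout as [read_coverage_file()].
#' @export
read_methylkit_file <- function(path, sample_id, tissue = NA_character_,
                                diet = NA_character_, sex = "unknown") {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("chr", "base", "coverage", "freqC")
  if (!all(need %in% names(raw))) {
    abort("methylKit raw file needs columns chr, base, coverage, freqC")
  }
  cm <- round(raw$coverage * raw$freqC / 100)
  new_methylome(raw$chr, raw$base, cm, raw$coverage - cm,
                sample_id, tissue, diet, sex)
}

new_methylome <- function(chrom, pos, count_meth, count_unmeth,
                          sample_id, tissue, diet, sex) {
  if (!is.na(diet) && !diet %in% .diets) {
    abort(paste0("unknown diet group: ", diet))
  }
  if (any(pos < 1)) abort("positions must be >= 1 (1-based)")
  tibble(sample_id = sample_id, tissue = tissue, diet = diet, sex = sex,
         chrom = as.character(chrom), pos = as.integer(pos),
         count_meth = as.integer(count_meth),
         count_unmeth = as.integer(count_unmeth)) %>%
    group_by(.data$sample_id, .data$tissue, .data$diet, .data$sex,
             .data$chrom, .data$pos) %>%
    summarise(count_meth = sum(.data$count_meth),
              count_unmeth = sum(.data$count_unmeth), .groups = "drop") %>%
    filter(.data$count_meth + .data$count_unmeth >= 1) %>%
    arrange(.data$chrom, .data$pos) %>%
    select(all_of(.cpg_cols))
}

#' Write a per-CpG count table in Bismark coverage format
#'
#' Inverse of [read_coverage_file()] for one sample; round-trips all
#' retained fields.
#'
#' @param methylome A per-CpG tibble for a single sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(methylome, path) {
  stopifnot(length(unique(methylome$sample_id)) <= 1)
  out <- methylome %>%
    mutate(start = .data$pos, end = .data$pos,
           percent = round(100 * .data$count_meth /
                             (.data$count_meth + .data$count_unmeth), 6)) %>%
    select("chrom", "start", "end", "percent", "count_meth", "count_unmeth")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge CpG dyads on opposite strands
#'
#' CpG sites are palindromic: bisulfite calls at position p (top strand)
#' and p + 1 (bottom strand) interrogate the same dyad. This merges each
#' record into the immediately preceding record at pos - 1 on the same
#' chromosome (counts summed). Off by default throughout the pipeline.
#'
#' @param methylomes Per-CpG tibble (one or more samples).
#' @return Destranded per-CpG tibble; merged dyads keep the lower position.
#' @export
destrand_cpgs <- function(methylomes) {
  methylomes %>%
    group_by(.data$sample_id, .data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(anchor = {
      a <- .data$pos
      adj <- c(FALSE, diff(.data$pos) == 1L)
      # a run of adjacent positions collapses onto its first member
      a[adj] <- a[which(adj) - 1L]
      a
    }) %>%
    ungroup() %>%
    group_by(.data$sample_id, .data$tissue, .data$diet, .data$sex,
             .data$chrom, pos = .data$anchor) %>%
    summarise(count_meth = sum(.data$count_meth),
              count_unmeth = sum(.data$count_unmeth), .groups = "drop") %>%
    arrange(.data$sample_id, .data$chrom, .data$pos) %>%
    select(all_of(.cpg_cols))
}

.dmt_bed_header <- c("chrom", "start", "end", "name", "delta", "direction",
                     "p_value", "q_value", "magnitude_bin")

#' Write called DMTs as a BED6+ file
#'
#' Coordinates are written 0-based half-open (as held in memory). An
#' empty DMT set yields a header-only file.
#'
#' @param dmts A DMT tibble from [call_dmts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmt_bed <- function(dmts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.dmt_bed_header, collapse = "\t")), con)
  if (nrow(dmts) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%s\t%.6g\t%.6g\t%s",
                     dmts$chrom, dmts$start, dmts$end,
                     paste0(dmts$chrom, ":", dmts$start, "-", dmts$end),
                     dmts$delta, as.character(dmts$direction),
                     dmts$p_value, dmts$q_value,
                     as.character(dmts$magnitude_bin))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a DMT BED file written by [write_dmt_bed()]
#'
#' @param path Path to a DMT BED6+ file.
#' @return A DMT tibble (chrom, start, end, delta, direction, p_value,
#'   q_value, magnitude_bin).
#' @export
read_dmt_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = .dmt_bed_header, comment = "#",
                         col_types = "ciicdcddc", progress = FALSE)
  raw %>%
    select(-"name") %>%
    mutate(direction = factor(.data$direction, c("hyper", "hypo")),
           magnitude_bin = factor(.data$magnitude_bin,
                                  c("10-15", "15-20", ">20")))
}

#' Read a gene model for tile annotation
#'
#' Accepts either a tab-separated table with header columns
#' `chrom, start, end, feature, gene_id, strand` (0-based half-open,
#' features among promoter/exon/intron/transcript) or a GTF/GFF file
#' (via rtracklayer, detected by extension). Promoters are derived from
#' transcript rows as a window around the transcription start site when
#' not given explicitly; introns are derived as transcript minus exons.
#'
#' @param path Input file.
#' @param promoter_upstream,promoter_downstream Promoter window around
#'   the TSS in bp (defaults 2000 upstream, 500 downstream).
#' @return A tibble of intervals: chrom, start, end, feature, gene_id,
#'   strand, with feature one of promoter/exon/intron.
#' @export
read_gene_model <- function(path, promoter_upstream = 2000,
                            promoter_downstream = 500) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF/GFF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    iv <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 feature = as.character(gr$type),
                 gene_id = if (!is.null(gr$gene_id)) gr$gene_id else NA,
                 strand = as.character(GenomicRanges::strand(gr)))
  } else {
    iv <- readr::read_tsv(path, col_types = "ciiccc", progress = FALSE)
    need <- c("chrom", "start", "end", "feature", "gene_id", "strand")
    if (!all(need %in% names(iv))) {
      abort("gene model table needs columns chrom, start, end, feature, gene_id, strand")
    }
  }
  if (any(iv$start >= iv$end)) {
    abort("gene model contains an interval with start >= end")
  }
  build_gene_model(iv, promoter_upstream, promoter_downstream)
}

build_gene_model <- function(iv, promoter_upstream = 2000,
                             promoter_downstream = 500) {
  iv <- mutate(iv, feature = tolower(.data$feature),
               start = as.integer(.data$start), end = as.integer(.data$end))
  tx <- filter(iv, .data$feature %in% c("transcript", "gene", "mrna"))
  out <- filter(iv, .data$feature %in% .features[1:3])
  if (nrow(tx) > 0) {
    if (!"promoter" %in% out$feature) {
      prom <- tx %>%
        mutate(tss = if_else(.data$strand == "-", .data$end, .data$start),
               start = if_else(.data$strand == "-",
                               .data$tss - as.integer(promoter_downstream),
                               .data$tss - as.integer(promoter_upstream)),
               end = if_else(.data$strand == "-",
                             .data$tss + as.integer(promoter_upstream),
                             .data$tss + as.integer(promoter_downstream)),
               start = pmax(.data$start, 0L), feature = "promoter") %>%
        select(-"tss")
      out <- bind_rows(out, prom)
    }
    if (!"intron" %in% out$feature && "exon" %in% out$feature) {
      introns <- derive_introns(tx, filter(out, .data$feature == "exon"))
      out <- bind_rows(out, introns)
    }
  }
  arrange(out, .data$chrom, .data$start) %>%
    select("chrom", "start", "end", "feature", "gene_id", "strand")
}

derive_introns <- function(tx, exons) {
  purrr::map_dfr(split(tx, tx$gene_id), function(t1) {
    ex <- exons %>% filter(.data$gene_id == t1$gene_id[1]) %>%
      arrange(.data$start)
    if (nrow(ex) < 2) return(tibble())
    tibble(chrom = t1$chrom[1],
           start = ex$end[-nrow(ex)], end = ex$start[-1],
           feature = "intron", gene_id = t1$gene_id[1],
           strand = t1$strand[1]) %>%
      filter(.data$start < .data$end)
  })
}

#' Read a 100-bp reference methylation track
#'
#' Tab-separated table with header `chrom, start, end, meth` where meth
#' is percent methylation in \[0, 100\] and regions sit on the 100-bp
#' tile grid (0-based half-open).
#'
#' @param path Input file.
#' @param source Track label, one of `"sperm"`, `"GVO"`, `"ICMm"`.
#' @return A tibble chrom, start, end, meth with attribute `source`.
#' @export
read_reference_track <- function(path, source = c("sperm", "GVO", "ICMm")) {
  source <- match.arg(source)
  x <- readr::read_tsv(path, col_types = "ciid", progress = FALSE)
  if (!all(c("chrom", "start", "end", "meth") %in% names(x))) {
    abort("reference track needs columns chrom, start, end, meth")
  }
  if (any(x$meth < 0 | x$meth > 100)) abort("meth must be within [0, 100]")
  attr(x, "source") <- source
  x
}

#' Read litter and embryo record tables
#'
#' Litter table columns: dam_id, diet, corpora_lutea, implantation_sites,
#' resorptions. Embryo table columns: dam_id, embryo_id, weight,
#' placenta_weight, sex, crown_rump, malformed.
#'
#' @param path Input file (tab-separated with header).
#' @return A validated tibble.
#' @export
read_litter_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("dam_id", "diet", "corpora_lutea", "implantation_sites",
            "resorptions")
  if (!all(need %in% names(x))) {
    abort(paste("litter table needs columns:", paste(need, collapse = ", ")))
  }
  if (any(x$resorptions > x$implantation_sites, na.rm = TRUE)) {
    abort("resorptions cannot exceed implantation sites")
  }
  x
}

#' @rdname read_litter_table
#' @export
read_embryo_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("dam_id", "weight")
  if (!all(need %in% names(x))) {
    abort("embryo table needs at least columns dam_id, weight")
  }
  if (any(x$weight <= 0, na.rm = TRUE)) abort("embryo weights must be > 0")
  x
}

#' Read targeted-assay input tables
#'
#' LUMA tables carry one row per digestion replicate with columns
#' sample_id, hpaii_ecori, mspi_ecori (peak ratios normalised by EcoRI).
#' Pyrosequencing tables are long: sample_id, gene, cpg_index, percent.
#'
#' @param path Input file (tab-separated with header).
#' @return A validated tibble.
#' @export
read_luma_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "hpaii_ecori", "mspi_ecori") %in% names(x))) {
    abort("LUMA table needs columns sample_id, hpaii_ecori, mspi_ecori")
  }
  x
}

#' @rdname read_luma_table
#' @export
read_pyro_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "gene", "percent") %in% names(x))) {
    abort("pyrosequencing table needs columns sample_id, gene, percent")
  }
  if (any(x$percent < 0 | x$percent > 100, na.rm = TRUE)) {
    abort("percent methylation must be within [0, 100]")
  }
  x
}
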