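#' Configuration for the synthetic-data generator
#'
#' Builds the full parameter set for simulating every input the pipeline
#' consumes: per-CpG bisulfite count tables for a 4-diet x 2-tissue
#' design, 100-bp reference methylation tracks (sperm, GVO, maternal-
#' allele ICM), a toy gene model, and litter/embryo records. The
#' defaults emulate the study design the pipeline targets: diets Ctrl /
#' 7FD / 10FS / 20FS, tissues placenta and cortex, 6 replicates per
#' group, planted differentially methylated tiles of 10-25 percentage
#' points, and a raised resorption rate in the 20FS group.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_chroms,chrom_len Toy genome: number of chromosomes and their
#'   length in bp.
#' @param cpg_density Expected CpGs per kb; CpGs are laid out in
#'   MspI-fragment-like clusters so covered 100-bp tiles typically hold
#'   2-5 CpGs, as in RRBS libraries.
#' @param n_replicates Samples per diet per tissue.
#' @param tissues,diets Character vectors of groups to simulate; the
#'   first diet is the control.
#' @param coverage_mean,coverage_size Per-CpG read coverage, negative
#'   binomial mean and size (coverage is floored at 1).
#' @param baseline_shape1,baseline_shape2 Beta parameters of the
#'   per-tile baseline methylation fraction (defaults give the bimodal
#'   methylome typical of RRBS).
#' @param rho Beta-binomial intra-class correlation of per-sample tile
#'   methylation around the tile baseline (biological replicate
#'   overdispersion).
#' @param n_planted Number of differentially methylated tiles planted
#'   per tissue.
#' @param planted_delta_range Absolute planted effect range in
#'   percentage points.
#' @param planted_hyper_fraction Fraction of planted effects that are
#'   methylation gains.
#' @param shared_fraction Fraction of planted tiles shared between the
#'   two tissues with concordant sign.
#' @param planted Optional explicit plan: tibble with columns tissue,
#'   chrom, start, diet, delta (percentage points). Overrides
#'   `n_planted`.
#' @param n_maternal Number of maternally inherited regions in the
#'   reference tracks.
#' @param maternal_class_probs Probabilities of the gain / stable / loss
#'   GVO to ICM dynamics among maternal regions.
#' @param gvo_high_fraction Fraction of maternal regions with GVO
#'   methylation >= 75 percent.
#' @param track_missing_fraction Fraction of non-maternal regions
#'   randomly dropped from one track (exercises the drop-if-missing
#'   rule).
#' @param litter_n Named integer vector, litters per diet.
#' @param cl_mean Mean corpora lutea per dam (Poisson).
#' @param preimp_p Per-ovulation probability of pre-implantation loss.
#' @param resorption_p Named per-diet probability that an implantation
#'   site resorbs.
#' @param embryo_weight_mean,embryo_weight_sd_within,embryo_weight_sd_between
#'   E18.5 embryo weight model in grams: grand mean, within-litter SD
#'   and between-litter SD.
#' @param placenta_weight_mean,placenta_weight_sd Placenta weight model
#'   in grams.
#' @param malformed_p Named per-diet probability of gross malformation
#'   per viable embryo.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 1e6, cpg_density = 10,
                       n_replicates = 6L,
                       tissues = c("placenta", "cortex"),
                       diets = c("Ctrl", "7FD", "10FS", "20FS"),
                       coverage_mean = 30, coverage_size = 5,
                       baseline_shape1 = 0.8, baseline_shape2 = 0.8,
                       rho = 0.005,
                       n_planted = 60L,
                       planted_delta_range = c(10, 25),
                       planted_hyper_fraction = 0.78,
                       shared_fraction = 0.09,
                       planted = NULL,
                       n_maternal = 300L,
                       maternal_class_probs = c(gain = 0.05, stable = 0.55,
                                                loss = 0.40),
                       gvo_high_fraction = 0.7,
                       track_missing_fraction = 0.02,
                       litter_n = c(Ctrl = 10L, `7FD` = 12L, `10FS` = 12L,
                                    `20FS` = 10L),
                       cl_mean = 11,
                       preimp_p = 0.12,
                       resorption_p = c(Ctrl = 0.05, `7FD` = 0.08,
                                        `10FS` = 0.08, `20FS` = 0.22),
                       embryo_weight_mean = 1.22,
                       embryo_weight_sd_within = 0.07,
                       embryo_weight_sd_between = 0.06,
                       placenta_weight_mean = 0.09,
                       placenta_weight_sd = 0.012,
                       malformed_p = c(Ctrl = 0.01, `7FD` = 0.03,
                                       `10FS` = 0.03, `20FS` = 0.05)) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)")
  probs <- c(preimp_p, resorption_p, malformed_p, maternal_class_probs,
             gvo_high_fraction, track_missing_fraction, shared_fraction,
             planted_hyper_fraction)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (any(planted_delta_range <= 0) || any(planted_delta_range >= 96)) {
    abort("planted deltas must lie in (0, 96) percentage points so tile methylation stays inside [0, 100]")
  }
  if (!is.null(planted)) {
    if (any(abs(planted$delta) >= 96)) {
      abort("planted deltas must keep tile methylation inside [0, 100]")
    }
    if (!all(planted$diet %in% diets[-1])) {
      abort("planted effects must target non-control diet groups")
    }
  }
  if (coverage_mean <= 0 || coverage_size <= 0) {
    abort("coverage parameters must be positive")
  }
  # restricting `diets` keeps only the matching litter parameters
  cfg$litter_n <- litter_n[names(litter_n) %in% diets]
  cfg$resorption_p <- resorption_p[names(resorption_p) %in% diets]
  cfg$malformed_p <- malformed_p[names(malformed_p) %in% diets]
  if (length(cfg$litter_n) == 0) abort("litter_n names must include a diet")
  if (!all(names(cfg$litter_n) %in% names(cfg$resorption_p)) ||
      !all(names(cfg$litter_n) %in% names(cfg$malformed_p))) {
    abort("resorption_p and malformed_p must cover every diet in litter_n")
  }
  structure(cfg, class = "sim_config")
}

# deterministic CpG landscape shared by both tissues: cluster tiles and
# per-tile CpG positions, derived from the seed alone
sim_landscape <- function(cfg) {
  withr::with_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_chroms), function(ci) {
      n_tiles_total <- floor(cfg$chrom_len / 100)
      k_mean <- 3  # CpGs per covered tile (1 + Poisson(2))
      n_covered <- min(n_tiles_total,
                       round(cfg$chrom_len / 1000 * cfg$cpg_density / k_mean))
      tiles <- sort(sample.int(n_tiles_total, n_covered) - 1L) * 100L
      k <- 1L + rpois(n_covered, 2)
      k <- pmin(k, 40L)
      tibble(chrom = paste0("chr", ci),
             start = rep(tiles, k),
             offset = unlist(lapply(k, function(kk)
               sort(sample.int(100L, kk))))) %>%
        mutate(pos = .data$start + .data$offset) %>%  # 1-based position
        select("chrom", "start", "pos")
    })
  })
}

# draw the planted-DMT plan (tile, tissue, diet, signed delta)
sim_plant_plan <- function(cfg, tile_tbl) {
  if (!is.null(cfg$planted)) return(as_tibble(cfg$planted))
  withr::with_seed(cfg$seed + 1L, {
    n_tiles <- nrow(tile_tbl)
    n_shared <- round(cfg$n_planted * cfg$shared_fraction)
    plans <- list()
    idx_shared <- sample.int(n_tiles, n_shared)
    taken <- idx_shared
    for (ts in cfg$tissues) {
      own <- sample(setdiff(seq_len(n_tiles), taken),
                    cfg$n_planted - n_shared)
      taken <- c(taken, own)
      idx <- c(idx_shared, own)
      sgn <- if_else(runif(length(idx)) < cfg$planted_hyper_fraction, 1, -1)
      mag <- runif(length(idx), cfg$planted_delta_range[1],
                   cfg$planted_delta_range[2])
      # shared tiles keep the sign drawn for the first tissue (concordance)
      if (ts != cfg$tissues[1] && n_shared > 0) {
        sgn[seq_len(n_shared)] <- plans[[1]]$sign_shared
      }
      plan <- tidyr::expand_grid(
        tibble(chrom = tile_tbl$chrom[idx], start = tile_tbl$start[idx],
               sign = sgn, mag = mag),
        diet = cfg$diets[-1]) %>%
        mutate(tissue = ts, delta = .data$sign * .data$mag) %>%
        select("tissue", "chrom", "start", "diet", "delta")
      plans[[length(plans) + 1]] <- list(plan = plan,
                                         sign_shared = sgn[seq_len(n_shared)])
    }
    bind_rows(purrr::map(plans, "plan"))
  })
}

#' Simulate per-CpG RRBS count tables with planted effects
#'
#' Generates one per-CpG methylome per tissue x diet x replicate on a
#' clustered toy genome. Per tile, a baseline methylation fraction is
#' drawn from a beta distribution; each sample's tile-level fraction is
#' a beta draw around that baseline with intra-class correlation `rho`
#' (biological overdispersion); per-CpG coverage is negative binomial
#' (floored at 1) and methylated counts are binomial in the sample's
#' tile fraction. Planted tiles add the configured delta in the affected
#' diet groups. Matched tissues share replicate ids and CpG landscape.
#'
#' @param cfg A [sim_config()].
#' @return A list with `methylomes` (long per-CpG tibble over all
#'   samples) and `truth` (tibble tissue, chrom, start, diet, delta of
#'   planted effects).
#' @export
sim_methylomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  land <- sim_landscape(cfg)
  tile_tbl <- distinct(land, .data$chrom, .data$start)
  plan <- sim_plant_plan(cfg, tile_tbl)

  samples <- tidyr::expand_grid(tissue = cfg$tissues, diet = cfg$diets,
                                rep = seq_len(cfg$n_replicates)) %>%
    mutate(sample_id = sprintf("%s_%s_r%02d", .data$tissue, .data$diet,
                               .data$rep),
           sex = "M")

  n_tiles <- nrow(tile_tbl)
  tile_id <- match(paste(land$chrom, land$start),
                   paste(tile_tbl$chrom, tile_tbl$start))

  out <- withr::with_seed(cfg$seed + 2L, {
    base <- rbeta(n_tiles, cfg$baseline_shape1, cfg$baseline_shape2)
    # planted tiles need headroom for the largest |delta| they carry
    if (nrow(plan) > 0) {
      pl_max <- plan %>%
        group_by(.data$chrom, .data$start) %>%
        summarise(dmax = max(.data$delta), dmin = min(.data$delta),
                  .groups = "drop")
      j <- match(paste(pl_max$chrom, pl_max$start),
                 paste(tile_tbl$chrom, tile_tbl$start))
      lo <- pmax(0.02, -pl_max$dmin / 100 + 0.02)
      hi <- pmin(0.98, 1 - pl_max$dmax / 100 - 0.02)
      if (any(lo >= hi)) abort("a planted delta pushes tile methylation outside [0, 100]")
      base[j] <- runif(length(j), lo, hi)
    }
    purrr::map_dfr(seq_len(nrow(samples)), function(si) {
      s <- samples[si, ]
      p_tile <- base
      if (nrow(plan) > 0) {
        hit <- plan %>% filter(.data$tissue == s$tissue, .data$diet == s$diet)
        if (nrow(hit) > 0) {
          j <- match(paste(hit$chrom, hit$start),
                     paste(tile_tbl$chrom, tile_tbl$start))
          p_tile[j] <- p_tile[j] + hit$delta / 100
        }
      }
      p_tile <- pmin(pmax(p_tile, 1e-4), 1 - 1e-4)
      a <- p_tile * (1 - cfg$rho) / cfg$rho
      b <- (1 - p_tile) * (1 - cfg$rho) / cfg$rho
      theta_tile <- rbeta(n_tiles, a, b)
      cov <- pmax(rnbinom(nrow(land), mu = cfg$coverage_mean,
                          size = cfg$coverage_size), 1L)
      m <- rbinom(nrow(land), cov, theta_tile[tile_id])
      tibble(sample_id = s$sample_id, tissue = s$tissue, diet = s$diet,
             sex = s$sex, chrom = land$chrom, pos = land$pos,
             count_meth = as.integer(m),
             count_unmeth = as.integer(cov - m))
    })
  })
  list(methylomes = out, truth = plan)
}

#' Simulate sperm / GVO / maternal-ICM reference methylation tracks
#'
#' Produces three 100-bp methylation tracks on the same tile grid as the
#' simulated methylomes. A designated subset of regions is maternally
#' inherited by construction (sperm <= 10 percent, GVO and ICMm >= 25 percent) and is
#' split among gain / stable / loss GVO-to-ICM dynamics with margins
#' away from every threshold, so the classifier must recover the truth
#' exactly. All remaining regions clearly fail at least one gate.
#'
#' @param cfg A [sim_config()].
#' @param tiles Optional tibble (chrom, start) of grid tiles; defaults
#'   to the covered tiles of the simulated CpG landscape.
#' @return A list with `tracks` (long tibble source, chrom, start, end,
#'   meth) and `truth` (tibble chrom, start, is_maternal, dynamic_class,
#'   gvo_high).
#' @export
sim_reference_tracks <- function(cfg, tiles = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(tiles)) {
    tiles <- distinct(sim_landscape(cfg), .data$chrom, .data$start)
  }
  n <- nrow(tiles)
  n_mat <- min(cfg$n_maternal, floor(n / 2))
  withr::with_seed(cfg$seed + 3L, {
    idx_mat <- sort(sample.int(n, n_mat))
    cls <- sample(names(cfg$maternal_class_probs), n_mat, replace = TRUE,
                  prob = cfg$maternal_class_probs)
    high <- runif(n_mat) < cfg$gvo_high_fraction

    gvo <- numeric(n_mat); icm <- numeric(n_mat)
    for (i in seq_len(n_mat)) {
      g <- if (high[i]) runif(1, 76, 96) else runif(1, 26, 74)
      if (cls[i] == "gain") {
        g <- min(g, 86)  # leave room for a >=12 pp rise with ICM <= 99
        icm[i] <- g + runif(1, 12, min(40, 99 - g))
      } else if (cls[i] == "loss") {
        g <- max(g, 40)  # leave room for a >=12 pp drop with ICM >= 25
        icm[i] <- g - runif(1, 12, min(40, g - 26))
      } else {
        icm[i] <- min(max(g + runif(1, -8, 8), 25.5), 99.5)
      }
      gvo[i] <- g
    }
    sperm_mat <- runif(n_mat, 0, 9.5)

    # non-maternal regions fail one gate with a clear margin
    idx_non <- setdiff(seq_len(n), idx_mat)
    fail_mode <- sample(1:3, length(idx_non), replace = TRUE)
    sperm_non <- if_else(fail_mode == 1, runif(length(idx_non), 13, 95),
                         runif(length(idx_non), 0, 9.5))
    gvo_non <- if_else(fail_mode == 2, runif(length(idx_non), 0, 22),
                       runif(length(idx_non), 27, 95))
    icm_non <- if_else(fail_mode == 3, runif(length(idx_non), 0, 22),
                       runif(length(idx_non), 27, 95))

    meth <- function(v_mat, v_non) {
      out <- numeric(n); out[idx_mat] <- v_mat; out[idx_non] <- v_non; out
    }
    grid <- tiles %>% mutate(end = .data$start + 100L)
    tracks <- bind_rows(
      mutate(grid, source = "sperm", meth = meth(sperm_mat, sperm_non)),
      mutate(grid, source = "GVO",   meth = meth(gvo, gvo_non)),
      mutate(grid, source = "ICMm",  meth = meth(icm, icm_non))) %>%
      select("source", "chrom", "start", "end", "meth")

    # drop a fraction of NON-maternal regions from the GVO track so the
    # drop-if-missing rule is exercised without touching the truth set
    if (cfg$track_missing_fraction > 0 && length(idx_non) > 0) {
      drop_n <- floor(length(idx_non) * cfg$track_missing_fraction)
      drop_idx <- sample(idx_non, drop_n)
      drop_keys <- paste(tiles$chrom[drop_idx], tiles$start[drop_idx])
      tracks <- tracks %>%
        filter(!(.data$source == "GVO" &
                   paste(.data$chrom, .data$start) %in% drop_keys))
    }

    truth <- tiles %>%
      mutate(is_maternal = FALSE, dynamic_class = NA_character_,
             gvo_high = NA)
    truth$is_maternal[idx_mat] <- TRUE
    truth$dynamic_class[idx_mat] <- cls
    truth$gvo_high[idx_mat] <- gvo >= 75
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a toy gene model on the synthetic genome
#'
#' Lays out non-overlapping genes with 2-8 exons on random strands and
#' returns promoter / exon / intron intervals in the layout produced by
#' [read_gene_model()].
#'
#' @param cfg A [sim_config()].
#' @param n_genes_per_chrom Genes per chromosome.
#' @return A gene-model tibble (chrom, start, end, feature, gene_id,
#'   strand).
#' @export
sim_gene_model <- function(cfg, n_genes_per_chrom = 25L) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 4L, {
    iv <- purrr::map_dfr(seq_len(cfg$n_chroms), function(ci) {
      slots <- floor(cfg$chrom_len / n_genes_per_chrom)
      purrr::map_dfr(seq_len(n_genes_per_chrom), function(gi) {
        g_start <- (gi - 1L) * slots + sample.int(round(slots * 0.2), 1)
        n_ex <- sample(2:8, 1)
        ex_len <- sample(100:300, n_ex, replace = TRUE)
        in_len <- sample(500:3000, n_ex - 1, replace = TRUE)
        starts <- g_start + cumsum(c(0L, ex_len[-n_ex] + in_len))
        strand <- sample(c("+", "-"), 1)
        gene_id <- sprintf("gene_chr%d_%03d", ci, gi)
        bind_rows(
          tibble(chrom = paste0("chr", ci), start = g_start,
                 end = starts[n_ex] + ex_len[n_ex], feature = "transcript",
                 gene_id = gene_id, strand = strand),
          tibble(chrom = paste0("chr", ci), start = starts,
                 end = starts + ex_len, feature = "exon",
                 gene_id = gene_id, strand = strand))
      })
    })
    build_gene_model(iv)
  })
}

#' Simulate litter and embryo records
#'
#' Per dam: corpora lutea are Poisson; implantations lose a binomial
#' pre-implantation fraction; resorptions are binomial per implantation
#' with a diet-dependent rate; viable embryos get normal weights with a
#' shared litter effect, sexes, crown-rump lengths, placenta weights and
#' malformation flags.
#'
#' @param cfg A [sim_config()].
#' @return A list with `litters` (dam-level counts) and `embryos`
#'   (embryo-level records), plus `truth` (the per-diet parameters
#'   used).
#' @export
sim_litters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 5L, {
    dams <- purrr::map_dfr(names(cfg$litter_n), function(d) {
      tibble(diet = d, dam = seq_len(cfg$litter_n[[d]]))
    }) %>%
      mutate(dam_id = sprintf("%s_d%02d", .data$diet, .data$dam))
    litters <- dams %>%
      mutate(corpora_lutea = rpois(n(), cfg$cl_mean),
             implantation_sites = .data$corpora_lutea -
               rbinom(n(), .data$corpora_lutea, cfg$preimp_p),
             resorptions = rbinom(n(), .data$implantation_sites,
                                  cfg$resorption_p[.data$diet]),
             viable = .data$implantation_sites - .data$resorptions) %>%
      select("dam_id", "diet", "corpora_lutea", "implantation_sites",
             "resorptions", "viable")
    embryos <- purrr::map_dfr(seq_len(nrow(litters)), function(i) {
      l <- litters[i, ]
      nv <- l$viable
      if (nv == 0) return(tibble())
      mu_litter <- cfg$embryo_weight_mean +
        rnorm(1, 0, cfg$embryo_weight_sd_between)
      w <- rnorm(nv, mu_litter, cfg$embryo_weight_sd_within)
      w <- pmax(w, 0.3)
      tibble(dam_id = l$dam_id, diet = l$diet,
             embryo_id = sprintf("%s_e%02d", l$dam_id, seq_len(nv)),
             weight = w,
             placenta_weight = pmax(rnorm(nv, cfg$placenta_weight_mean,
                                          cfg$placenta_weight_sd), 0.02),
             sex = sample(c("M", "F"), nv, replace = TRUE),
             crown_rump = 22 + 8 * (w - cfg$embryo_weight_mean) +
               rnorm(nv, 0, 0.5),
             malformed = runif(nv) < cfg$malformed_p[l$diet])
    })
    list(litters = litters, embryos = embryos,
         truth = tibble(diet = names(cfg$resorption_p),
                        resorption_p = unname(cfg$resorption_p),
                        malformed_p = unname(cfg$malformed_p[names(cfg$resorption_p)])))
  })
}
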