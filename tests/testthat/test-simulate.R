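small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_len = 2e5, cpg_density = 10,
             tissues = "placenta", diets = c("Ctrl", "7FD"),
             n_planted = 0L, ...)
}

test_that("the generator is fully determined by its seed", {
  a <- sim_methylomes(small_cfg())
  b <- sim_methylomes(small_cfg())
  expect_identical(a, b)
  c <- sim_methylomes(small_cfg(seed = 8))
  expect_false(identical(a$methylomes, c$methylomes))
  expect_identical(sim_litters(small_cfg())$litters,
                   sim_litters(small_cfg())$litters)
  expect_identical(sim_reference_tracks(small_cfg())$tracks,
                   sim_reference_tracks(small_cfg())$tracks)
})

test_that("simulated counts respect conservation invariants", {
  mm <- sim_methylomes(small_cfg())$methylomes
  expect_true(all(mm$count_meth >= 0))
  expect_true(all(mm$count_unmeth >= 0))
  expect_true(all(mm$count_meth + mm$count_unmeth >= 1))
  lit <- sim_litters(small_cfg())$litters
  expect_true(all(lit$implantation_sites <= lit$corpora_lutea))
  expect_true(all(lit$resorptions <= lit$implantation_sites))
})

test_that("null simulations have near-zero between-group tile deltas", {
  cfg <- sim_config(seed = 11, n_chroms = 1L, chrom_len = 6e5,
                    cpg_density = 10, tissues = "placenta",
                    diets = c("Ctrl", "7FD"), n_planted = 0L)
  res <- sim_methylomes(cfg)$methylomes %>%
    aggregate_tiles() %>%
    test_tiles(treatment = "7FD")
  expect_gt(nrow(res), 1000)
  expect_lt(abs(mean(res$delta)), 1)
})

test_that("a planted +20 pp tile is recovered without bias at its true delta", {
  # single planted tile per rerun. The recovered pooled delta has a
  # sampling floor set by the generative model itself: per-sample tile
  # fraction variance p(1-p) * (rho + (1 + (n-1) rho) / n) with n reads
  # per sample per tile (~30 x 1-5 CpGs), giving a between-group delta
  # SD of roughly 3-6 pp at 6v6. The frozen expectations are therefore
  # unbiasedness (mean over reruns near +20) and spread inside that
  # model-implied envelope.
  deltas <- purrr::map_dbl(1:40, function(s) {
    cfg <- sim_config(seed = 100 + s, n_chroms = 1L, chrom_len = 1e5,
                      cpg_density = 10, tissues = "placenta",
                      diets = c("Ctrl", "7FD"),
                      planted_delta_range = c(20, 20),
                      planted_hyper_fraction = 1, shared_fraction = 0,
                      n_planted = 1L)
    truth <- sim_methylomes(cfg)
    res <- truth$methylomes %>% aggregate_tiles() %>%
      test_tiles(treatment = "7FD")
    hit <- dplyr::semi_join(res, truth$truth, by = c("chrom", "start"))
    if (nrow(hit) == 1) hit$delta else NA_real_
  })
  # a planted tile is untestable mainly when it drew a single CpG
  # (P(k = 1) = exp(-2) = 13.5%), so ~86.5% testable is expected;
  # 0.75 allows 2 SD of binomial noise at 40 reruns
  expect_gte(mean(!is.na(deltas)), 0.75)
  expect_lt(abs(mean(deltas, na.rm = TRUE) - 20), 2)
  expect_lt(sd(deltas, na.rm = TRUE), 7)
})

test_that("reference tracks satisfy the maternal gates by construction", {
  rt <- sim_reference_tracks(small_cfg())
  wide <- tidyr::pivot_wider(rt$tracks, names_from = "source",
                             values_from = "meth")
  truth <- dplyr::inner_join(rt$truth, wide, by = c("chrom", "start"))
  mat <- dplyr::filter(truth, is_maternal)
  expect_true(all(mat$sperm <= 10))
  expect_true(all(mat$GVO >= 25 & mat$ICMm >= 25))
  stable <- dplyr::filter(mat, dynamic_class == "stable")
  expect_true(all(abs(stable$GVO - stable$ICMm) < 10))
  gain <- dplyr::filter(mat, dynamic_class == "gain")
  expect_true(all(gain$ICMm - gain$GVO >= 10))
  expect_true(all(mat$ICMm <= 100 & mat$GVO <= 100))
})

test_that("litter outcomes respond to the configured resorption rates", {
  cfg <- sim_config(seed = 3, litter_n = c(Ctrl = 250L, `20FS` = 250L),
                    diets = c("Ctrl", "20FS"),
                    resorption_p = c(Ctrl = 0.05, `20FS` = 0.22))
  lit <- sim_litters(cfg)$litters
  means <- lit %>% dplyr::group_by(diet) %>%
    dplyr::summarise(m = mean(resorptions))
  expect_gt(means$m[means$diet == "20FS"], means$m[means$diet == "Ctrl"])
})

test_that("dams with zero corpora lutea have zero downstream counts", {
  cfg <- sim_config(seed = 5, cl_mean = 0.4,
                    litter_n = c(Ctrl = 200L, `7FD` = 5L, `10FS` = 5L,
                                 `20FS` = 5L))
  lit <- sim_litters(cfg)$litters
  zero <- dplyr::filter(lit, corpora_lutea == 0)
  expect_gt(nrow(zero), 0)
  expect_true(all(zero$implantation_sites == 0))
  expect_true(all(zero$resorptions == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(rho = 0), "rho")
  expect_error(sim_config(resorption_p = c(Ctrl = -0.1, `7FD` = 0.1,
                                           `10FS` = 0.1, `20FS` = 0.1)),
               "probabilities")
  expect_error(sim_config(planted_delta_range = c(10, 99)), "planted deltas")
  expect_error(sim_config(planted = tibble::tibble(
    tissue = "placenta", chrom = "chr1", start = 0L, diet = "Ctrl",
    delta = 20)), "non-control")
})
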