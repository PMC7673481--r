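test_that("tile methylation is the unweighted mean of CpG fractions", {
  mm <- make_methylome("s1", "chr1", c(110, 150, 190),
                       m = c(0, 10, 30), u = c(20, 10, 0))
  tiles <- aggregate_tiles(mm)
  expect_equal(nrow(tiles), 1)
  expect_equal(tiles$start, 100L)
  expect_equal(tiles$end, 200L)
  expect_equal(tiles$meth, 50)            # mean of 0, 50, 100 percent
  expect_equal(tiles$coverage, 70L)
  expect_equal(tiles$n_cpgs, 3L)
})

test_that("tiles are assigned on the 0-based 100-bp grid at boundaries", {
  mm <- make_methylome("s1", "chr1", c(100, 101, 200), m = c(1, 1, 1),
                       u = c(1, 1, 1))
  tiles <- aggregate_tiles(mm)
  # pos 100 is the last base of tile [0,100); 101 and 200 fall in [100,200)
  expect_equal(tiles$start, c(0L, 100L))
  expect_equal(tiles$n_cpgs, c(1L, 2L))
})

test_that("unsorted input is sorted internally with a warning", {
  mm <- make_methylome("s1", "chr1", c(150, 110), m = c(5, 5), u = c(5, 5))
  expect_warning(tiles <- aggregate_tiles(mm), "not sorted")
  expect_equal(tiles$n_cpgs, 2L)
  expect_equal(nrow(aggregate_tiles(mm[0, ])), 0)
})

test_that("filters drop tiles below the CpG and coverage thresholds", {
  base <- make_tile_samples(m_ctrl = c(5, 5), cov_ctrl = c(20, 20),
                            m_treat = c(5, 5), cov_treat = c(20, 20))
  # a second tile with a single CpG in every sample
  one_cpg <- base %>% dplyr::filter(pos == 10) %>%
    dplyr::mutate(pos = pos + 1000L)
  # a third tile where one sample has total coverage 9
  low_cov <- base %>% dplyr::mutate(
    pos = pos + 2000L,
    count_unmeth = dplyr::if_else(sample_id == "Ctrl_r1" & pos == 2010,
                                  3L, count_unmeth),
    count_meth = dplyr::if_else(sample_id == "Ctrl_r1" & pos == 2060,
                                1L, count_meth),
    count_unmeth = dplyr::if_else(sample_id == "Ctrl_r1" & pos == 2060,
                                  0L, count_unmeth))
  res <- aggregate_tiles(dplyr::bind_rows(base, one_cpg, low_cov)) %>%
    test_tiles(treatment = "7FD")
  expect_equal(res$start, 0L)  # only the full tile survives
  low_tile <- aggregate_tiles(low_cov) %>%
    dplyr::filter(sample_id == "Ctrl_r1")
  expect_lt(low_tile$coverage, 10)
})

test_that("Fisher path: identical pooled counts give p = 1, extremes vanish", {
  same <- make_tile_samples(m_ctrl = 5, cov_ctrl = 10, m_treat = 5,
                            cov_treat = 10)
  res <- aggregate_tiles(same) %>% test_tiles(treatment = "7FD")
  expect_equal(res$p_value, 1)

  extreme <- make_tile_samples(m_ctrl = 100, cov_ctrl = 100,
                               m_treat = 0, cov_treat = 100,
                               cpg_offsets = c(10L, 60L))
  res2 <- aggregate_tiles(extreme) %>% test_tiles(treatment = "7FD")
  # pooled 200/0 vs 0/200 methylated/unmethylated
  expect_lt(res2$p_value, 1e-20)
})

test_that("1v1 p-values equal the hypergeometric oracle", {
  set.seed(42)
  for (i in 1:25) {
    cc <- sample(10:60, 1); ct <- sample(10:60, 1)
    mc <- rbinom(1, cc, runif(1)); mt <- rbinom(1, ct, runif(1))
    mm <- make_tile_samples(m_ctrl = mc, cov_ctrl = cc, m_treat = mt,
                            cov_treat = ct)
    res <- aggregate_tiles(mm) %>% test_tiles(treatment = "7FD")
    # the tile pools its two identical CpGs, doubling every count
    expect_equal(res$p_value,
                 fisher_oracle(2 * mc, 2 * (cc - mc), 2 * mt, 2 * (ct - mt)),
                 tolerance = 1e-10)
  }
})

test_that("replicated-design p equals the binomial glm likelihood-ratio test", {
  set.seed(7)
  for (i in 1:12) {
    cov_c <- sample(15:50, 4, replace = TRUE)
    cov_t <- sample(15:50, 4, replace = TRUE)
    m_c <- rbinom(4, cov_c, 0.4)
    m_t <- rbinom(4, cov_t, runif(1, 0.3, 0.8))
    mm <- make_tile_samples(m_ctrl = m_c, cov_ctrl = cov_c,
                            m_treat = m_t, cov_treat = cov_t)
    res <- aggregate_tiles(mm) %>% test_tiles(treatment = "7FD")
    # oracle: explicit glm fit, deviance-difference chi-square test.
    # counts per sample are doubled across the tile's two CpGs
    grp <- factor(rep(c("c", "t"), each = 4))
    fit <- stats::glm(cbind(2 * c(m_c, m_t),
                            2 * c(cov_c - m_c, cov_t - m_t)) ~ grp,
                      family = stats::binomial())
    p_glm <- stats::pchisq(fit$null.deviance - fit$deviance, 1,
                           lower.tail = FALSE)
    expect_equal(res$p_value, p_glm, tolerance = 1e-8)
  }
})

test_that("group-label symmetry negates delta and preserves p", {
  mm <- make_tile_samples(m_ctrl = c(5, 8, 6), cov_ctrl = c(20, 25, 18),
                          m_treat = c(15, 12, 17), cov_treat = c(21, 19, 26))
  tiles <- aggregate_tiles(mm)
  fwd <- test_tiles(tiles, treatment = "7FD", control = "Ctrl")
  rev <- test_tiles(tiles, treatment = "Ctrl", control = "7FD")
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the worked example", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.004), 0.004)
  # NA p-values are excluded from m and returned as NA
  q <- adjust_fdr(c(0.01, NA, 0.02, 0.03))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.03, 0.03, 0.03))
  # monotone non-decreasing in sorted-p order
  set.seed(1)
  p <- runif(50)
  q2 <- adjust_fdr(p)
  expect_true(all(diff(q2[order(p)]) >= -1e-12))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMT calling applies strict q and delta thresholds with bins", {
  res <- structure(tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L, 300L, 400L),
    end = start + 100L, n_cpgs = 2L, cov_ctrl = 100, cov_treat = 100,
    meth_ctrl = 50, meth_treat = 50, mean_meth_ctrl = 50,
    mean_meth_treat = 50,
    delta = c(12, 30, -9.5, 10, -22),
    p_value = 1e-4, q_value = c(0.005, 0.02, 0.001, 0.005, 0.0099)),
    class = c("tile_dm", "tbl_df", "tbl", "data.frame"))
  dmts <- call_dmts(res)
  expect_equal(dmts$start, c(0L, 400L))  # q fail, |delta| fails drop out
  expect_equal(as.character(dmts$direction), c("hyper", "hypo"))
  expect_equal(as.character(dmts$magnitude_bin), c("10-15", ">20"))

  # boundary cases are NOT DMTs: q exactly at threshold, delta exactly 10
  edge <- res %>% dplyr::mutate(q_value = c(0.01, 0.005, 0.005, 0.005,
                                            0.01),
                                delta = c(12, 10, 10, 10, -15))
  expect_equal(nrow(call_dmts(edge)), 0)
})

test_that("DMT summaries count directions and magnitude bins", {
  res <- structure(tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L, 300L), end = start + 100L,
    n_cpgs = 2L, cov_ctrl = 100, cov_treat = 100, meth_ctrl = 50,
    meth_treat = 50, mean_meth_ctrl = 50, mean_meth_treat = 50,
    delta = c(12, 14, 13, -11), p_value = 1e-5, q_value = 1e-4),
    class = c("tile_dm", "tbl_df", "tbl", "data.frame"))
  s <- summarize_dmts(call_dmts(res))
  expect_equal(attr(s, "hyper_fraction"), 0.75)
  expect_equal(s$total, c(4L, 0L, 0L))  # all |delta| in (10,15]
  expect_equal(glance(s)$n_dmts, 4L)
  empty <- summarize_dmts(call_dmts(res[0, ]))
  expect_equal(attr(empty, "n"), 0L)
  expect_null(attr(empty, "hyper_fraction"))
})

test_that("overdispersion scaling never decreases the p-value", {
  set.seed(9)
  cov <- sample(20:40, 12, replace = TRUE)
  m <- rbinom(12, cov, rep(c(0.3, 0.5), each = 6))
  mm <- make_tile_samples(m_ctrl = m[1:6], cov_ctrl = cov[1:6],
                          m_treat = m[7:12], cov_treat = cov[7:12])
  tiles <- aggregate_tiles(mm)
  plain <- test_tiles(tiles, treatment = "7FD")
  od <- test_tiles(tiles, treatment = "7FD", overdispersion = TRUE)
  expect_gte(od$p_value, plain$p_value)
})
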