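mk_litters <- function(diet, cl, imp, res) {
  tibble::tibble(dam_id = sprintf("%s_d%02d", diet, seq_along(cl)),
                 diet = diet, corpora_lutea = cl,
                 implantation_sites = imp, resorptions = res)
}

test_that("pre- and post-implantation losses follow their definitions", {
  lit <- mk_litters("Ctrl", cl = c(10, 8, NA), imp = c(8, 8, 6),
                    res = c(2, 0, 6))
  out <- litter_outcomes(lit)
  expect_equal(out$preimp_loss, c(2L, 0L, NA_integer_))
  expect_equal(out$postimp_loss, c(2L, 0L, 6L))  # resorption count
  expect_equal(out$viable, c(6L, 8L, 0L))
  lit_lit <- litter_outcomes(lit, postimplantation = "literal")
  expect_equal(lit_lit$postimp_loss, c(6L, 8L, 0L))  # implants - resorptions

  # CL miscount: floored at zero with a warning, not an error
  expect_warning(out2 <- litter_outcomes(mk_litters("Ctrl", 7, 8, 0)),
                 "floored")
  expect_equal(out2$preimp_loss, 0L)
  expect_error(litter_outcomes(mk_litters("Ctrl", 10, 5, 6)),
               "exceed")
})

test_that("growth classification uses 2 SDs of control litter mean weights", {
  litters <- dplyr::bind_rows(
    mk_litters("Ctrl", cl = rep(10, 3), imp = rep(8, 3), res = rep(0, 3)),
    mk_litters("20FS", cl = 10, imp = 8, res = 0))
  # control litter means 1.1, 1.2, 1.3 -> mu = 1.2, sd = 0.1
  embryos <- tibble::tibble(
    dam_id = rep(litters$dam_id[1:3], each = 2),
    weight = c(1.05, 1.15, 1.15, 1.25, 1.25, 1.35))
  test_embryos <- tibble::tibble(dam_id = "20FS_d01",
                                 weight = c(0.95, 1.45, 1.0, 1.4, 1.2))
  cls <- classify_growth(dplyr::bind_rows(embryos, test_embryos), litters)
  got <- tail(as.character(cls$growth_class), 5)
  # thresholds 1.0 and 1.4 are strict: boundary weights stay normal
  expect_equal(got, c("restricted", "enhanced", "normal", "normal",
                      "normal"))
  expect_equal(attr(cls, "mu"), 1.2)
  expect_equal(attr(cls, "sigma"), 0.1)

  expect_error(classify_growth(embryos[1:2, ], litters[1, ]),
               "two control litters")
})

test_that("growth classification is translation equivariant", {
  litters <- mk_litters("Ctrl", cl = rep(10, 3), imp = rep(8, 3),
                        res = rep(0, 3))
  set.seed(4)
  embryos <- tibble::tibble(dam_id = sample(litters$dam_id, 30,
                                            replace = TRUE),
                            weight = rnorm(30, 1.2, 0.15))
  a <- classify_growth(embryos, litters)
  b <- classify_growth(dplyr::mutate(embryos, weight = weight + 0.5),
                       litters)
  expect_equal(as.character(a$growth_class), as.character(b$growth_class))
  expect_equal(attr(b, "mu"), attr(a, "mu") + 0.5)
  expect_equal(attr(b, "sigma"), attr(a, "sigma"))
})

test_that("abnormal counts add resorptions and abnormal growth per litter", {
  litters <- mk_litters(c("Ctrl", "Ctrl"), cl = c(10, 10), imp = c(8, 8),
                        res = c(1, 0))
  emb <- tibble::tibble(
    dam_id = c("Ctrl_d01", "Ctrl_d02"),
    weight = c(1, 1),
    growth_class = factor(c("restricted", "normal"),
                          c("normal", "restricted", "enhanced")))
  flags <- count_abnormal(litters, emb)
  expect_equal(flags$n_abnormal, c(2L, 0L))     # 1 resorption + 1 restricted
  expect_equal(flags$flagged, c(TRUE, FALSE))   # flagged needs > 1
})

test_that("the abnormal-litter Fisher test matches exact enumeration", {
  mk_flags <- function(diet, n, k) {
    tibble::tibble(diet = diet, flagged = rep(c(TRUE, FALSE), c(k, n - k)))
  }
  # perfectly balanced table -> p = 1
  bal <- dplyr::bind_rows(mk_flags("Ctrl", 2, 1), mk_flags("7FD", 2, 1))
  expect_equal(abnormal_litter_test(bal)$p_value, 1)

  # [[5,0],[0,5]]: full hypergeometric enumeration gives 2/252
  ext <- dplyr::bind_rows(mk_flags("Ctrl", 5, 0), mk_flags("7FD", 5, 5))
  expect_equal(abnormal_litter_test(ext)$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(abnormal_litter_test(ext)$p_value,
               fisher_oracle(5, 0, 0, 5), tolerance = 1e-12)

  # exchangeable under swapping the two rows
  sw <- dplyr::bind_rows(mk_flags("Ctrl", 5, 5), mk_flags("7FD", 5, 0))
  expect_equal(abnormal_litter_test(sw)$p_value,
               abnormal_litter_test(ext)$p_value)

  # per-diet comparisons when not pooled
  three <- dplyr::bind_rows(mk_flags("Ctrl", 10, 4), mk_flags("7FD", 12, 8),
                            mk_flags("20FS", 10, 8))
  per <- abnormal_litter_test(three, pool_treated = FALSE)
  expect_equal(nrow(per), 2)
  expect_error(abnormal_litter_test(mk_flags("Ctrl", 5, 1)), "treated")
})

test_that("Dunnett comparisons are bounded by raw and Bonferroni p-values", {
  set.seed(21)
  d <- tibble::tibble(
    diet = rep(c("Ctrl", "7FD", "10FS", "20FS"), each = 8),
    value = rnorm(32, 10, 2) + rep(c(0, 0.5, 1.5, 3), each = 8))
  dn <- dunnett_vs_control(d)
  expect_equal(dn$group, c("7FD", "10FS", "20FS"))
  # independent per-contrast t from the pooled one-way model
  k <- 4; n_per <- 8; df_err <- k * n_per - k
  mse <- sum(stats::resid(stats::aov(value ~ diet, d))^2) / df_err
  raw <- purrr::map_dbl(dn$group, function(g) {
    t <- (mean(d$value[d$diet == g]) - mean(d$value[d$diet == "Ctrl"])) /
      sqrt(mse * 2 / n_per)
    2 * stats::pt(-abs(t), df_err)
  })
  # raw p <= Dunnett p <= Bonferroni p (small numeric slack for the
  # quasi-Monte-Carlo multivariate-t integration)
  expect_true(all(dn$p_value >= raw - 1e-4))
  expect_true(all(dn$p_value <= pmin(1, raw * (k - 1)) + 1e-4))
  # a 10-sigma shifted group is detected despite adjustment
  d2 <- d %>% dplyr::mutate(value = value +
                              ifelse(diet == "20FS", 20, 0))
  expect_lt(dunnett_vs_control(d2)$p_value[3], 0.001)

  # identical constants: no effect anywhere
  flat <- tibble::tibble(diet = rep(c("Ctrl", "7FD"), each = 3),
                         value = 5)
  expect_equal(dunnett_vs_control(flat)$p_value, 1)
  expect_error(dunnett_vs_control(
    tibble::tibble(diet = c("Ctrl", "Ctrl", "7FD"), value = 1:3)),
    "two observations")
})
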