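# small in-code fixtures shared across test files

# per-CpG tibble for one sample from parallel vectors
make_methylome <- function(sample_id, chrom, pos, m, u, diet = "Ctrl",
                           tissue = "placenta", sex = "M") {
  tibble::tibble(sample_id = sample_id, tissue = tissue, diet = diet,
                 sex = sex, chrom = chrom, pos = as.integer(pos),
                 count_meth = as.integer(m), count_unmeth = as.integer(u))
}

# a two-group methylome set with every CpG of a tile sharing the given
# per-sample methylated/total counts; cpg_offsets are within-tile positions
make_tile_samples <- function(m_ctrl, cov_ctrl, m_treat, cov_treat,
                              start = 0L, cpg_offsets = c(10L, 60L),
                              treat = "7FD") {
  stopifnot(length(m_ctrl) == length(cov_ctrl),
            length(m_treat) == length(cov_treat))
  mk <- function(m, cov, diet, i) {
    make_methylome(sprintf("%s_r%d", diet, i), "chr1",
                   start + cpg_offsets,
                   rep(m, length(cpg_offsets)),
                   rep(cov - m, length(cpg_offsets)), diet = diet)
  }
  dplyr::bind_rows(
    purrr::map2_dfr(m_ctrl, seq_along(m_ctrl),
                    function(m, i) mk(m, cov_ctrl[i], "Ctrl", i)),
    purrr::map2_dfr(m_treat, seq_along(m_treat),
                    function(m, i) mk(m, cov_treat[i], treat, i)))
}

# independent two-sided Fisher oracle by hypergeometric enumeration:
# sum of probabilities of all tables (given margins) at most as likely
# as the observed one
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# deviance of the two-group binomial model, written independently of
# the package (saturated-in-group log-likelihood difference)
lrt_oracle_stat <- function(m1, c1, m2, c2) {
  ll <- function(M, C) {
    p <- M / C
    out <- 0
    if (M > 0) out <- out + M * log(p)
    if (C > M) out <- out + (C - M) * log(1 - p)
    out
  }
  2 * (ll(sum(m1), sum(c1)) + ll(sum(m2), sum(c2)) -
         ll(sum(m1) + sum(m2), sum(c1) + sum(c2)))
}

# reference track tibble on the 100-bp grid
make_track <- function(start, meth, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + 100L, meth = meth)
}

# minimal gene model rows
gm_row <- function(chrom, start, end, feature, gene_id = "g1",
                   strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), feature = feature,
                 gene_id = gene_id, strand = strand)
}
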