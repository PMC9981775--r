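roh_test_cfg <- function(...) {
  # small-scale config used for oracle work: the window scan reduces to
  # exact run enumeration when no missing calls are allowed per window
  # and the hit threshold is below 1/window_snps
  roh_config(window_snps = 20, window_max_het = 0,
             window_max_missing = 0, window_hit_threshold = 0.01,
             min_length_bp = 1e6, min_snps = 15,
             min_density_bp_per_snp = 150e3, max_gap_bp = 500e3, ...)
}

test_that("scanned regions follow the gap, count and density criteria", {
  cfg <- roh_config()
  # uniform 100-kb spacing over 10 Mb: whole extent scannable
  m <- marker_map(paste0("L", 1:100), "1", seq(1e5, 1e7, by = 1e5))
  sc <- scanned_regions(m, cfg)
  expect_equal(nrow(sc$regions), 1)
  expect_equal(sc$total_bp, 1e7 - 1e5 + 1)
  # a 600-kb gap splits the chromosome into two scanned regions
  pos <- c(seq(1e5, 1e7, by = 1e5), seq(1.06e7, 2.05e7, by = 1e5))
  m2 <- marker_map(paste0("L", seq_along(pos)), "1", pos)
  sc2 <- scanned_regions(m2, cfg)
  expect_equal(nrow(sc2$regions), 2)
  expect_true(all(sc2$regions$end_bp[1] <= 1e7,
                  sc2$regions$start_bp[2] >= 1.06e7))
})

test_that("scanned totals equal the brute-force pair enumeration", {
  cfg <- roh_test_cfg()
  set.seed(51)
  for (rep in 1:20) {
    pos <- sort(sample(seq(1e4, 2e7, by = 1e4), 60))
    m <- marker_map(paste0("L", seq_along(pos)), "1", pos)
    sc <- scanned_regions(m, cfg)
    expect_equal(sc$total_bp, scanned_oracle_one(pos, cfg))
  }
})

test_that("ROH detection handles the canonical degenerate cases", {
  cfg <- roh_config()
  # all-heterozygous sample: no segments
  pos <- seq(1e5, 1e7, by = 1e5)
  g <- toy_genotypes(matrix(1L, 1, 100), pos = pos)
  expect_equal(nrow(detect_roh(g, cfg)), 0)
  # fully homozygous chromosome: 80 SNPs over 8 Mb, one segment
  g2 <- toy_genotypes(matrix(0L, 1, 80), pos = seq(1e5, 8e6, by = 1e5))
  segs <- detect_roh(g2, cfg)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, 1e5)
  expect_equal(segs$end_bp, 8e6)
  expect_equal(segs$n_snps, 80)
  # a homozygous run of only 4 Mb flanked by heterozygotes: below 5 Mb
  d3 <- matrix(1L, 1, 100)
  d3[1, 30:69] <- 0L  # 40 SNPs over 3.9 Mb
  g3 <- toy_genotypes(d3, pos = pos)
  expect_equal(nrow(detect_roh(g3, cfg)), 0)
  # short chromosomes are skipped with a warning
  g4 <- toy_genotypes(matrix(0L, 1, 10), pos = seq(1e5, 1e6, by = 1e5))
  expect_warning(detect_roh(g4, cfg), "fewer than")
})

test_that("window detection equals the exhaustive run scanner", {
  cfg <- roh_test_cfg()
  set.seed(52)
  for (rep in 1:25) {
    nl <- 200
    pos <- sort(sample(seq(2e4, 3e7, by = 2e4), nl))
    # mostly homozygous genome so runs of useful length occur
    d <- matrix(sample(c(0L, 2L, 1L), nl, replace = TRUE,
                       prob = c(.55, .4, .05)), 1, nl)
    g <- toy_genotypes(d, pos = pos)
    segs <- suppressWarnings(detect_roh(g, cfg))
    oracle <- roh_oracle_one(d[1, ], pos, cfg)
    expect_equal(nrow(segs), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(segs$start_bp, oracle$start_bp)
      expect_equal(segs$end_bp, oracle$end_bp)
      expect_equal(segs$n_snps, oracle$n_snps)
    }
  }
})

test_that("segments never overlap within a sample", {
  cfg <- roh_test_cfg()
  set.seed(53)
  nl <- 400
  pos <- sort(sample(seq(2e4, 6e7, by = 2e4), nl))
  d <- matrix(sample(c(0L, 2L, 1L), 5 * nl, replace = TRUE,
                     prob = c(.55, .4, .05)), 5, nl)
  g <- toy_genotypes(d, pos = pos)
  segs <- suppressWarnings(detect_roh(g, cfg))
  for (id in unique(segs$sample_id)) {
    s <- segs[segs$sample_id == id, ]
    s <- s[order(s$start_bp), ]
    if (nrow(s) > 1)
      expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
})

test_that("F_ROH arithmetic and length-threshold monotonicity hold", {
  segs <- data.frame(sample_id = c("S1", "S1", "S2"),
                     chromosome = "1",
                     start_bp = c(1, 1, 1),
                     end_bp = c(1e7, 6e6, 4e6),
                     n_snps = c(100, 60, 40),
                     length_bp = c(1e7, 6e6, 4e6))
  fr <- f_roh(segs, c("S1", "S2", "S3"), scanned_total_bp = 1e8,
              min_length = 5e6)
  expect_equal(fr$f_roh, c(0.16, 0, 0))
  # a sample with no segments scores zero, not NA
  expect_equal(fr$f_roh[fr$sample_id == "S3"], 0)
  # raising the length threshold never increases f_roh
  fr2 <- f_roh(segs, c("S1", "S2", "S3"), 1e8, min_length = 8e6)
  expect_true(all(fr2$f_roh <= fr$f_roh))
  expect_error(f_roh(segs, "S1", 0), "positive")
  # one 10-Mb segment over 100 Mb scanned
  fr3 <- f_roh(segs[1, ], "S1", 1e8)
  expect_equal(fr3$f_roh, 0.1)
})

test_that("inbred classes follow the pedigree-expectation thresholds", {
  segs <- data.frame(sample_id = "S1", chromosome = "1", start_bp = 1,
                     end_bp = 13e6, n_snps = 130, length_bp = 13e6)
  fr <- f_roh(segs, "S1", 1e8)
  expect_equal(fr$inbred_class, "half_siblings_or_more")
  expect_equal(f_roh(segs, "S1", 2e8)$inbred_class, "full_cousins")
  expect_equal(f_roh(segs, "S1", 4e8)$inbred_class, "half_cousins")
  expect_equal(f_roh(segs, "S1", 8e8)$inbred_class, "below")
})
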