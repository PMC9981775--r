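test_that("call-rate filtering removes failing loci then samples", {
  set.seed(1)
  d <- matrix(sample(0:2, 100, replace = TRUE), 5, 20)
  g <- toy_genotypes(d)
  cfg <- qc_config()
  # complete data passes untouched
  expect_equal(dim(filter_call_rate(g, cfg)$dosage), c(5L, 20L))
  # a sample missing 10% of loci fails the 0.95 threshold (the loci it
  # misses still pass theirs: 39/40 = 0.975)
  d2 <- matrix(sample(0:2, 40 * 100, replace = TRUE), 40, 100)
  d2[1, 1:10] <- NA
  g2 <- toy_genotypes(d2)
  out <- filter_call_rate(g2, cfg)
  expect_false("S1" %in% out$samples$sample_id)
  expect_equal(n_samples(out), 39)
  expect_equal(n_loci(out), 100)
})

test_that("engineered missingness matrix filters to the hand-enumerated set", {
  # 5 samples x 20 loci; loci 1-2 fail locus call rate (2/5 and 3/5
  # missing); after their removal sample 5 is missing 2 of 18 (0.889)
  d <- matrix(1L, 5, 20)
  d[c(1, 2), 1] <- NA
  d[c(1, 2, 3), 2] <- NA
  d[5, c(3, 4)] <- NA
  g <- toy_genotypes(d)
  cfg <- qc_config(min_locus_call_rate = 0.7, min_sample_call_rate = 0.95)
  out <- filter_call_rate(g, cfg)
  expect_setequal(out$markers$locus_id, paste0("L", 3:20))
  expect_setequal(out$samples$sample_id, paste0("S", 1:4))
  # brute-force check of the same rule
  keep_l <- colMeans(!is.na(d)) >= 0.7
  keep_s <- rowMeans(!is.na(d[, keep_l])) >= 0.95
  expect_equal(n_samples(out), sum(keep_s))
  expect_equal(n_loci(out), sum(keep_l))
})

test_that("filters refuse to return an empty cohort silently", {
  # every sample misses one call on loci that survive the locus filter
  d <- matrix(1L, 3, 4)
  diag(d) <- NA
  cfg <- qc_config(min_locus_call_rate = 0.5,
                   min_sample_call_rate = 0.95)
  expect_error(filter_call_rate(toy_genotypes(d), cfg), "all samples")
})

test_that("minor allele frequency follows the direct count", {
  g <- toy_genotypes(rbind(c(2, 0, 0), c(2, 1, 0), c(2, 2, 1)))
  maf <- minor_allele_frequency(g)
  expect_equal(unname(maf), c(0, 0.5, 1 / 6))
  # MAF is invariant under allele-orientation flips
  expect_equal(minor_allele_frequency(flip_alleles(g)), maf)
  expect_error(allele_b_frequency(g, sample_subset = integer(0)),
               "empty")
})

test_that("call-rate and MAF filters are idempotent", {
  set.seed(3)
  d <- matrix(sample(c(0:2, NA), 400, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 20, 20)
  g <- toy_genotypes(d)
  cfg <- qc_config(min_locus_call_rate = 0.85,
                   min_sample_call_rate = 0.6, min_maf = 0.1)
  f1 <- filter_call_rate(g, cfg)
  f2 <- filter_call_rate(f1, cfg)
  expect_identical(f2$dosage, f1$dosage)
  m1 <- filter_maf(f1, cfg)
  m2 <- filter_maf(m1, cfg)
  expect_identical(m2$dosage, m1$dosage)
})

test_that("LD pruning keeps one of a duplicated locus pair", {
  set.seed(4)
  x <- sample(0:2, 100, replace = TRUE, prob = c(.25, .5, .25))
  d <- cbind(x, x, sample(0:2, 100, replace = TRUE))
  g <- toy_genotypes(d)
  kept <- ld_prune(g, qc_config(ld_r2_max = 0.2, ld_window_snps = 50,
                                ld_step_snps = 5))
  expect_length(intersect(kept, c("L1", "L2")), 1)
  expect_true("L3" %in% kept)
})

test_that("independently simulated loci survive pruning at r2 < 0.5", {
  set.seed(5)
  d <- matrix(rbinom(200 * 40, 2, 0.4), 200, 40)
  g <- toy_genotypes(d)
  kept <- ld_prune(g, qc_config(ld_r2_max = 0.5))
  expect_equal(length(kept), 40)
})

test_that("pruned output satisfies its own r2 contract post hoc", {
  set.seed(6)
  base <- matrix(rbinom(80 * 10, 2, 0.5), 80, 10)
  # duplicate noisy copies to create dependency blocks
  noisy <- base
  flip <- matrix(runif(length(base)) < 0.1, nrow(base))
  noisy[flip] <- sample(0:2, sum(flip), replace = TRUE)
  d <- cbind(base, noisy)[, order(rep(1:10, 2))]
  g <- toy_genotypes(d)
  cfg <- qc_config(ld_r2_max = 0.2, ld_window_snps = 10, ld_step_snps = 2)
  kept <- ld_prune(g, cfg)
  ki <- match(kept, g$markers$locus_id)
  for (s in seq(1, n_loci(g), by = cfg$ld_step_snps)) {
    orig <- s:min(s + cfg$ld_window_snps - 1, n_loci(g))
    win <- intersect(orig, ki)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(g$dosage[, win]))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), cfg$ld_r2_max + 1e-12)
  }
})

test_that("5-locus toy pruning matches the exhaustive retained set", {
  # engineered so every pruning order leaves the same retained set:
  # L1=L2=L3 mutually r2=1, L4 and L5 independent of everything
  set.seed(8)
  x <- sample(0:2, 60, replace = TRUE, prob = c(.3, .4, .3))
  d <- cbind(x, x, x,
             sample(0:2, 60, replace = TRUE),
             sample(0:2, 60, replace = TRUE))
  g <- toy_genotypes(d)
  kept <- ld_prune(g, qc_config(ld_r2_max = 0.3, ld_window_snps = 5,
                                ld_step_snps = 2))
  # brute force: all maximal subsets with pairwise r2 <= 0.3 keep exactly
  # one of {L1, L2, L3} plus L4, L5
  expect_length(kept, 3)
  expect_length(intersect(kept, c("L1", "L2", "L3")), 1)
  expect_true(all(c("L4", "L5") %in% kept))
})

test_that("intragenic exclusion matches an interval-membership oracle", {
  set.seed(9)
  pos <- sort(sample(1:10000, 20))
  g <- toy_genotypes(matrix(1L, 2, 20), pos = pos)
  iv <- gene_interval_set(rep("1", 3), c(500, 3000, 7000),
                          c(1500, 4000, 9000))
  kept <- exclude_intragenic(g, iv)
  oracle <- !((pos > 500 & pos <= 1500) | (pos > 3000 & pos <= 4000) |
                (pos > 7000 & pos <= 9000))
  expect_setequal(kept, g$markers$locus_id[oracle])
  # disjoint chromosome naming is an error, not a silent no-op
  iv2 <- gene_interval_set("chr1", 1, 10000)
  expect_error(exclude_intragenic(g, iv2), "chromosome")
})
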