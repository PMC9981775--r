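test_that("pure-genotype simulation matches binomial moments", {
  expect_true(all(simulate_pure_genotypes(rep(0, 50), 5)$dosage == 0))
  expect_true(all(simulate_pure_genotypes(rep(1, 50), 5)$dosage == 2))
  g <- simulate_pure_genotypes(rep(0.3, 1), 2000, seed = 31)
  m <- mean(g$dosage)
  v <- var(as.numeric(g$dosage))
  se_m <- sqrt(0.42 / 2000)
  expect_lt(abs(m - 0.6), 3 * se_m)
  expect_lt(abs(v - 0.42), 0.1)
  expect_equal(unique(g$samples$group), "simulated_pure")
  expect_error(simulate_pure_genotypes(c(0.5, 1.2), 5), "\\[0, 1\\]")
})

test_that("Hamming distances follow the allele-mismatch definition", {
  g <- toy_genotypes(rbind(c(0, 1, 2), c(1, 1, 0), c(0, 1, 2)))
  dm <- hamming_distance_matrix(g)
  expect_equal(dm["S1", "S3"], 0)          # identical samples
  expect_equal(dm["S1", "S2"], 0.5)        # (1 + 0 + 2) / (2 * 3)
  g2 <- toy_genotypes(rbind(c(0, 0), c(2, 2)))
  expect_equal(hamming_distance_matrix(g2)["S1", "S2"], 1)
  # missing loci drop out of the pair's denominator
  g3 <- toy_genotypes(rbind(c(0, NA, 2), c(1, 1, 2)))
  expect_equal(hamming_distance_matrix(g3)["S1", "S2"], 1 / 4)
  # a pair with no shared typed loci is an error naming the pair
  g4 <- toy_genotypes(rbind(c(0, NA), c(NA, 1)))
  expect_error(hamming_distance_matrix(g4), "S1")
})

test_that("Hamming matrix is symmetric and satisfies the triangle inequality", {
  set.seed(32)
  d <- matrix(sample(c(0:2, NA), 20 * 100, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 20, 100)
  dm <- hamming_distance_matrix(toy_genotypes(d))
  expect_equal(dm, t(dm))
  n <- nrow(dm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("PCoA embeds collinear and Euclidean configurations exactly", {
  # three collinear points: d(1,2) = d(2,3) = 1, d(1,3) = 2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  ord <- pcoa_ordination(d)
  expect_equal(ord$axis_count, 1)
  expect_equal(dist(ord$coordinates[, 1])[1:3],
               dist(c(0, 1, 2))[1:3], tolerance = 1e-9,
               ignore_attr = TRUE)
  # Euclidean distances from random 2-D points are reproduced
  set.seed(33)
  xy <- matrix(rnorm(16), 8, 2)
  de <- as.matrix(dist(xy))
  ord2 <- pcoa_ordination(de, max_axes = 7)
  expect_equal(as.matrix(dist(ord2$coordinates)), de, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(ord2$negative_eigenvalue_mass, 1e-9)
  # identical samples land on coincident coordinates
  d2 <- as.matrix(dist(c(0, 0, 5)))
  ord3 <- pcoa_ordination(d2)
  expect_equal(ord3$coordinates[1, ], ord3$coordinates[2, ])
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(34)
  d <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  ours <- pcoa_ordination(d, max_axes = 5)
  ref <- ape::pcoa(d)
  for (k in 1:3) {
    expect_equal(abs(ours$coordinates[, k]),
                 abs(ref$vectors[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("projection endpoints rescale to 0 and 1", {
  co <- rbind(c(0, 0), c(4, 2), c(2, 1), c(0.4, 0.2), c(1, -2))
  ord <- structure(list(coordinates = co), class = "pcoa_result")
  s <- sample_table(paste0("S", 1:5),
                    c("simulated_pure", "pig_reference", "wild", "wild",
                      "wild"))
  sc <- project_f_hybrid(ord, s)
  expect_equal(sc$f_hybrid[1], 0)
  expect_equal(sc$f_hybrid[2], 1)
  expect_equal(sc$f_hybrid[3], 0.5)   # halfway along the axis
  expect_equal(sc$f_hybrid[4], 0.1)
  # orthogonal displacement does not change the score
  expect_equal(sc$f_hybrid[5],
               sum(c(1, -2) * c(4, 2)) / sum(c(4, 2)^2))
  expect_equal(sc$hybrid_class,
               c("none", "gen2_or_more", "gen2_or_more", "gen4", "none"))
  # coincident centroids are an error
  s2 <- s; s2$group <- c("simulated_pure", "simulated_pure",
                         "pig_reference", "pig_reference", "wild")
  co2 <- co; co2[3:4, ] <- co2[1:2, ]
  ord2 <- structure(list(coordinates = co2), class = "pcoa_result")
  expect_error(project_f_hybrid(ord2, s2), "coincide")
})

test_that("hybrid classes use the backcross-generation boundaries", {
  expect_equal(classify_hybrid(c(0.05, 0.0625, 0.1, 0.125, 0.2, 0.250,
                                 0.26, -0.1)),
               c("none", "gen4", "gen4", "gen3", "gen3", "gen3",
                 "gen2_or_more", "none"))
})

test_that("diagnostic alleles straddle both pool thresholds", {
  set.seed(35)
  nl <- 50
  pw <- runif(nl, 0, 0.5)
  pp <- runif(nl, 0, 0.5)
  pw[1:5] <- 0.01; pp[1:5] <- 0.30      # diagnostic on allele b
  pw[6] <- 0.99; pp[6] <- 0.60          # diagnostic on allele a
  mk <- marker_map(paste0("L", 1:nl), "1", seq_len(nl) * 1e5)
  wild <- sample_genotypes(pw, 300, seed = 36, markers = mk)
  pigs <- sample_genotypes(pp, 300, seed = 37, group = "pig_reference",
                           markers = mk)
  das <- diagnostic_alleles(wild, pigs)
  # threshold oracle on realised pool frequencies
  fw <- allele_b_frequency(wild); fp <- allele_b_frequency(pigs)
  oracle <- union(
    which(fw < 0.025 & fp > 0.225),
    which((1 - fw) < 0.025 & (1 - fp) > 0.225))
  expect_setequal(das$locus_id, paste0("L", oracle))
  # identical spectra yield an empty set
  das0 <- diagnostic_alleles(wild, wild)
  expect_equal(nrow(das0), 0)
})

test_that("diagnostic-allele clustering flags adjacency, not load", {
  mk <- marker_map(paste0("L", 1:40), rep(c("1", "2"), each = 20),
                   rep(seq_len(20) * 1e6, 2))
  das <- data.frame(locus_id = paste0("L", 1:40),
                    diagnostic_allele = "b",
                    wild_freq = 0.01, pig_freq = 0.3)
  # carrier at 8 adjacent loci on chromosome 1
  d <- matrix(0L, 1, 40)
  d[1, 3:10] <- 1L
  g <- genotype_matrix(d, mk, sample_table("S1", "wild"))
  pr <- diagnostic_allele_profile(g, "S1", das, window_mb = 10,
                                  n_perm = 500, seed = 38)
  expect_equal(pr$carrier_fraction, 8 / 40)
  expect_equal(pr$cluster_score, 8)
  expect_lt(pr$p_value, 0.05)
  # same load scattered across both chromosomes: no clustering signal
  d2 <- matrix(0L, 1, 40)
  d2[1, c(1, 6, 11, 16, 21, 26, 31, 36)] <- 1L
  g2 <- genotype_matrix(d2, mk, sample_table("S1", "wild"))
  pr2 <- diagnostic_allele_profile(g2, "S1", das, window_mb = 10,
                                   n_perm = 500, seed = 38)
  expect_equal(pr2$carrier_fraction, 8 / 40)
  expect_gt(pr2$p_value, 0.2)
  # no carried alleles
  g3 <- genotype_matrix(matrix(0L, 1, 40), mk, sample_table("S1", "wild"))
  pr3 <- diagnostic_allele_profile(g3, "S1", das, n_perm = 500)
  expect_equal(pr3$carrier_fraction, 0)
  expect_equal(pr3$p_value, 1)
})

test_that("cohort-level carrier fractions separate pigs from wild boar", {
  set.seed(39)
  nl <- 400
  anc <- runif(nl, 0.05, 0.95); F <- 0.2
  pw <- rbeta(nl, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  pp <- rbeta(nl, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  mk <- marker_map(paste0("L", 1:nl), "1", seq_len(nl) * 1e5)
  wild <- sample_genotypes(pw, 100, seed = 40, markers = mk)
  pigs <- sample_genotypes(pp, 100, seed = 41, group = "pig_reference",
                           markers = mk)
  das <- diagnostic_alleles(wild, pigs)
  expect_gt(nrow(das), 0)
  cf <- function(g, ids) {
    mean(vapply(ids, function(id)
      diagnostic_allele_profile(g, id, das, n_perm = 100,
                                seed = 1)$carrier_fraction, numeric(1)))
  }
  cf_pig <- cf(pigs, pigs$samples$sample_id[1:10])
  cf_wild <- cf(wild, wild$samples$sample_id[1:10])
  expect_gt(cf_pig, cf_wild)
})
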