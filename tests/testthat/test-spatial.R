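test_that("per-location downsampling caps cohort sizes reproducibly", {
  s <- sample_table(paste0("S", 1:40), "wild",
                    location_id = rep(c("A", "B", "C"), c(3, 26, 11)))
  keep <- downsample_per_location(s, max_n = 5, seed = 81)
  tab <- table(s$location_id[match(keep, s$sample_id)])
  expect_equal(unname(tab[["A"]]), 3)
  expect_equal(unname(tab[["B"]]), 5)
  expect_equal(unname(tab[["C"]]), 5)
  expect_identical(keep, downsample_per_location(s, max_n = 5, seed = 81))
  expect_false(identical(keep,
                         downsample_per_location(s, max_n = 5, seed = 82)))
})

test_that("inbred and hybrid exclusion applies both thresholds", {
  hy <- data.frame(sample_id = paste0("S", 1:5),
                   f_hybrid = c(0, 0.07, 0.02, 0.0625, 0.3))
  ib <- data.frame(sample_id = paste0("S", 1:5),
                   f_roh = c(0, 0.01, 0.10, 0.0625, 0))
  keep <- exclude_inbred_and_hybrid(hy, ib)
  # S2 (hybrid 0.07), S3 (inbred 0.10), S5 (hybrid 0.3) removed;
  # scores exactly at 0.0625 are retained (rule is strictly greater)
  expect_setequal(keep, c("S1", "S4"))
  expect_setequal(exclude_inbred_and_hybrid(
    data.frame(sample_id = "S1", f_hybrid = 0),
    data.frame(sample_id = "S1", f_roh = 0)), "S1")
})

test_that("great-circle distances follow the haversine closed form", {
  s <- sample_table(c("a", "b", "c"), "wild",
                    longitude = c(0, 180, 0), latitude = c(0, 0, 0))
  dm <- geographic_distance_matrix(s)
  expect_equal(dm["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(dm["a", "c"], 0)
  expect_equal(dm, t(dm))
  s2 <- sample_table("a", "wild")
  expect_error(geographic_distance_matrix(s2), "a")
})

test_that("Mantel r is 1 for proportional matrices and p is calibrated", {
  set.seed(83)
  xy <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(xy))
  m <- mantel_test(d, 3.7 * d, n_perm = 99)
  expect_equal(m$r, 1)
  expect_lte(m$p_value, 0.05)
  expect_error(mantel_test(d[1:2, 1:2], d[1:2, 1:2]), "at least 3")
})

test_that("exact Mantel p at n = 4 equals full enumeration", {
  set.seed(84)
  d1 <- as.matrix(dist(rnorm(4)))
  d2 <- as.matrix(dist(rnorm(4)))
  m <- mantel_test(d1, d2, exact = TRUE)
  # independent enumeration over all 24 permutations
  pm <- perms_oracle(4)
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut])
  rs <- apply(pm, 1, function(p) {
    dp <- d1[p, p]
    cor(dp[ut], d2[ut])
  })
  p_oracle <- sum(abs(rs) >= abs(r_obs) - 1e-12) / nrow(pm)
  expect_equal(m$p_value, p_oracle)
  expect_equal(m$n_permutations, 24)
})

test_that("Mantel r agrees with the vegan reference statistic", {
  skip_if_not_installed("vegan")
  set.seed(85)
  d1 <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  ours <- mantel_test(d1, d2, n_perm = 99)
  ref <- vegan::mantel(d1, d2, permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("location-mean distances collapse the individual matrix", {
  d <- matrix(0, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  d[1, 3] <- d[3, 1] <- 2; d[1, 4] <- d[4, 1] <- 4
  d[2, 3] <- d[3, 2] <- 6; d[2, 4] <- d[4, 2] <- 8
  d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  s <- sample_table(paste0("S", 1:4), "wild",
                    location_id = c("A", "A", "B", "B"))
  dp <- location_mean_distance(d, s)
  expect_equal(dp["A", "B"], 5)  # mean of 2, 4, 6, 8
  expect_equal(diag(dp), c(A = 0, B = 0))
})

test_that("axis-geography correlation recovers rank agreement", {
  co <- cbind(seq(-3, 2), c(2, 0, 1, -1, 3, -2))
  ord <- structure(list(coordinates = co), class = "pcoa_result")
  s <- sample_table(paste0("S", 1:6), "wild",
                    location_id = paste0("L", 1:6),
                    longitude = seq(-10, 15, length.out = 6),
                    latitude = c(44, 41, 43, 40, 46, 39))
  res <- axis_geography_correlation(ord, s)
  r11 <- res[res$axis == "axis1" & res$geo_variable == "longitude", ]
  expect_equal(r11$spearman_rho, 1)
  # hand rank computation for axis2 ~ latitude
  rho_hand <- cor(rank(co[, 2]), rank(s$latitude))
  r22 <- res[res$axis == "axis2" & res$geo_variable == "latitude", ]
  expect_equal(r22$spearman_rho, rho_hand)
  # constant axis flags a degenerate correlation
  ordc <- structure(list(coordinates = cbind(rep(1, 6), co[, 2])),
                    class = "pcoa_result")
  resc <- axis_geography_correlation(ordc, s)
  expect_true(all(resc$degenerate[resc$axis == "axis1"]))
  expect_true(all(is.na(resc$spearman_rho[resc$axis == "axis1"])))
})

test_that("multilocus heterozygosity counts typed loci only", {
  g <- toy_genotypes(rbind(rep(1L, 10),
                           rep(0L, 10),
                           c(rep(1L, 3), rep(0L, 7)),
                           c(1L, 1L, rep(NA, 8))))
  h <- mlh(g)
  expect_equal(h$mlh, c(1, 0, 0.3, 1))
  expect_equal(h$n_typed, c(10, 10, 10, 2))
  # invariant under allele-orientation flips
  expect_equal(mlh(flip_alleles(g))$mlh, h$mlh)
  g$dosage[4, ] <- NA
  expect_warning(h2 <- mlh(g), "S4")
  expect_true(is.na(h2$mlh[4]))
})

test_that("MLH deciles split samples into equal-count classes", {
  set.seed(86)
  d <- matrix(rbinom(100 * 200, 2, 0.5), 100, 200)
  h <- mlh(toy_genotypes(d))
  expect_true(all(table(h$decile) == 10))
  expect_equal(sort(unique(h$decile)), 1:10)
  # deciles are ordered by heterozygosity
  expect_lte(max(h$mlh[h$decile == 1]), min(h$mlh[h$decile == 10]))
})

test_that("the MLH linear model recovers noiseless and signed effects", {
  set.seed(87)
  n <- 120
  df <- data.frame(longitude = runif(n, -10, 25),
                   latitude = runif(n, 38, 55),
                   f_hybrid = runif(n, 0, 0.3),
                   f_roh = runif(n, 0, 0.2))
  df$mlh <- 0.2 + 0.004 * df$longitude
  fit <- mlh_linear_model(df)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "longitude"], 0.004,
               tolerance = 1e-10)
  expect_gt(fit$r2_adj, 0.9999)
  expect_equal(fit$df_residual, n - 4)
  # built-in negative F_ROH effect: sign recovered under noise
  df$mlh <- 0.25 + 0.004 * df$longitude + 0.2 * df$f_hybrid -
    0.56 * df$f_roh + rnorm(n, 0, 0.01)
  fit2 <- mlh_linear_model(df)
  co2 <- fit2$coefficients
  expect_lt(co2$estimate[co2$term == "f_roh"], 0)
  expect_gt(co2$estimate[co2$term == "f_hybrid"], 0)
  # collinear designs are refused
  df$f_roh <- df$longitude * 2
  expect_error(mlh_linear_model(df), "collinear")
})

test_that("F-test p-values are uniform under a pure-noise response", {
  set.seed(88)
  pv <- replicate(200, {
    n <- 40
    df <- data.frame(longitude = runif(n), latitude = runif(n),
                     f_hybrid = runif(n), f_roh = runif(n),
                     mlh = rnorm(n))
    fit <- mlh_linear_model(df)
    f <- fit$F_statistic
    pf(f, 3, fit$df_residual, lower.tail = FALSE)
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("regional allele selection follows the locally-major rule", {
  # locus 1: globally minor allele (b) is major in the focal region
  # locus 2: allele at 0.6 everywhere is not minor at panel scale
  # locus 3: globally minor and also minor in focal region
  freqs <- rbind(c(0.60, 0.60, 0.05),   # focal population
                 c(0.05, 0.60, 0.05),
                 c(0.05, 0.60, 0.05))
  mk <- marker_map(paste0("L", 1:3), "1", 1:3 * 1000)
  model <- population_model(3, fst = 0, n_loci = 3)
  g <- sample_genotypes(freqs, 200, model = model, seed = 89,
                        markers = mk)
  sel <- select_regional_alleles(g, g$samples, focal = "pop1")
  expect_equal(sel$locus_id, "L1")
  expect_equal(sel$allele, "b")
  expect_gt(sel$focal_freq, 0.5)
  mrf <- mean_regional_frequency(g, g$samples, sel)
  # focal region's own mean frequency exceeds 0.5 by construction
  expect_gt(mrf$mean_freq[mrf$location_id == "pop1"], 0.5)
  expect_lt(mrf$mean_freq[mrf$location_id == "pop2"], 0.2)
  # direct computation oracle
  p2 <- mean(g$dosage[g$samples$location_id == "pop2", "L1"]) / 2
  expect_equal(mrf$mean_freq[mrf$location_id == "pop2"], p2)
})

test_that("synthetic cline data yields a positive, significant Mantel r", {
  set.seed(90)
  hits <- 0
  for (rep in 1:5) {
    model <- population_model(8, fst = 0.02, n_loci = 400,
                              cline = list(direction = c(1, 0),
                                           strength = 1))
    bn <- balding_nichols_freqs(model, seed = 900 + rep)
    g <- sample_genotypes(bn$freqs, 5, model = model, seed = 910 + rep)
    dm <- hamming_distance_matrix(g)
    dp <- location_mean_distance(dm, g$samples)
    loc <- unique(as.data.frame(g$samples)[c("location_id", "longitude",
                                             "latitude")])
    loc <- loc[match(rownames(dp), loc$location_id), ]
    dg <- geographic_distance_matrix(sample_table(
      loc$location_id, "wild", loc$location_id, loc$longitude,
      loc$latitude))
    m <- mantel_test(dp, dg, n_perm = 199, seed = rep)
    if (m$r > 0 && m$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
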