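#' Simulate "pure" reference genotypes from allele frequencies
#'
#' Draws, independently per locus, dosages from Binomial(2, freq): the
#' construction used to anchor the wild end of the ordination axis in the
#' PCoA-projection hybrid estimator. `freq` is the frequency of the counted
#' allele, typically estimated per genetic cluster from putatively
#' unadmixed wild samples (the cluster-level MAF when alleles are oriented
#' so the counted allele is the wild-minor one).
#'
#' @param freq_by_locus numeric vector of counted-allele frequencies.
#' @param n number of simulated individuals (study design: 20).
#' @param markers optional [marker_map()]; a generic one is built if
#'   omitted.
#' @param seed RNG seed for reproducibility.
#' @param prefix sample-id prefix.
#' @return a [genotype_matrix()] with group `"simulated_pure"`.
#' @export
simulate_pure_genotypes <- function(freq_by_locus, n = 20, markers = NULL,
                                    seed = NULL, prefix = "pure") {
  if (any(is.na(freq_by_locus)) ||
      any(freq_by_locus < 0 | freq_by_locus > 1))
    stop("simulate_pure_genotypes: frequencies must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nl <- length(freq_by_locus)
  d <- matrix(stats::rbinom(n * nl, 2, rep(freq_by_locus, each = n)),
              nrow = n, ncol = nl)
  if (is.null(markers))
    markers <- marker_map(paste0("L", seq_len(nl)), "1", seq_len(nl))
  sm <- sample_table(sprintf("%s_%02d", prefix, seq_len(n)),
                     group = "simulated_pure")
  genotype_matrix(d, markers, sm)
}

#' Pairwise Hamming genetic distances
#'
#' d(i, j) = sum over pairwise-non-missing loci of |dosage_i - dosage_j|,
#' normalised by twice the number of such loci, so opposite homozygotes
#' count 2 mismatching alleles and distances lie in \[0, 1\].
#'
#' @param g a [genotype_matrix()] with at least two samples.
#' @return a symmetric numeric matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
hamming_distance_matrix <- function(g) {
  if (n_samples(g) < 2)
    stop("hamming_distance_matrix: need at least 2 samples")
  d <- g$dosage
  a0 <- (!is.na(d) & d == 0L) * 1
  a1 <- (!is.na(d) & d == 1L) * 1
  a2 <- (!is.na(d) & d == 2L) * 1
  # mismatch count: |di-dj| = 1 for {0,1} and {1,2} pairs, 2 for {0,2}
  num <- tcrossprod(a0, a1) + tcrossprod(a1, a0) +
    tcrossprod(a1, a2) + tcrossprod(a2, a1) +
    2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0))
  shared <- tcrossprod(a0 + a1 + a2)
  if (any(shared[upper.tri(shared)] == 0)) {
    bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("hamming_distance_matrix: samples ",
         rownames(d)[bad[1]], " and ", rownames(d)[bad[2]],
         " share no non-missing loci")
  }
  dm <- num / (2 * shared)
  diag(dm) <- 0
  dimnames(dm) <- list(rownames(d), rownames(d))
  dm
}

#' Classical principal coordinates analysis
#'
#' Metric ordination of a distance matrix: double-centre -D^2/2,
#' eigendecompose, scale eigenvectors by the square root of their
#' eigenvalues (via [stats::cmdscale()]). Axes with non-positive
#' eigenvalues are dropped; their absolute eigenvalue mass is reported as
#' a diagnostic of non-Euclidean input.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param max_axes maximum number of axes to retain.
#' @return a list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (positive, decreasing), `axis_count`,
#'   `negative_eigenvalue_mass`.
#' @export
pcoa_ordination <- function(d, max_axes = 10) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("pcoa_ordination: distance matrix must be symmetric")
  k <- min(max_axes, nrow(d) - 1)
  mds <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  eig <- mds$eig
  pos <- eig[eig > 1e-12]
  n_axes <- min(k, length(pos))
  coords <- mds$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  res <- list(
    coordinates = coords,
    eigenvalues = pos[seq_len(n_axes)],
    axis_count = n_axes,
    negative_eigenvalue_mass = sum(abs(eig[eig < 0])) / sum(abs(eig))
  )
  class(res) <- "pcoa_result"
  res
}

#' Hybrid-index projection (F_hybrid)
#'
#' Projects each sample onto the polar axis running from the centroid of
#' the simulated pure wild genotypes to the centroid of the pig reference
#' genotypes, in the space of the leading ordination axes. Scores are
#' affinely rescaled so the pure centroid maps to 0 and the pig centroid
#' to 1; they are deliberately not clamped, preserving over-/under-shoot.
#' Classification thresholds follow backcross expectations: F_hybrid of
#' 0.25, 0.125 and 0.0625 are the expected fractions for 2nd, 3rd and 4th
#' generation hybrids.
#'
#' @param ord a [pcoa_ordination()] result over pig references, simulated
#'   pure genotypes, and focal samples jointly.
#' @param samples a [sample_table()] aligned with the ordination rows.
#' @param axes_used number of leading axes spanning the projection space
#'   (default 2).
#' @return data.frame with columns `sample_id`, `group`, `f_hybrid`,
#'   `hybrid_class`.
#' @export
project_f_hybrid <- function(ord, samples, axes_used = 2) {
  co <- ord$coordinates
  axes_used <- min(axes_used, ncol(co))
  co <- co[, seq_len(axes_used), drop = FALSE]
  if (nrow(co) != nrow(samples))
    stop("project_f_hybrid: ordination rows != sample rows")
  is_pig <- samples$group == "pig_reference"
  is_pure <- samples$group == "simulated_pure"
  if (!any(is_pig) || !any(is_pure))
    stop("project_f_hybrid: need both pig_reference and simulated_pure ",
         "samples in the ordination")
  c_pure <- colMeans(co[is_pure, , drop = FALSE])
  c_pig <- colMeans(co[is_pig, , drop = FALSE])
  v <- c_pig - c_pure
  len2 <- sum(v^2)
  if (len2 < 1e-12)
    stop("project_f_hybrid: pure and pig centroids coincide")
  f <- as.numeric((sweep(co, 2, c_pure) %*% v) / len2)
  data.frame(
    sample_id = samples$sample_id,
    group = samples$group,
    f_hybrid = f,
    hybrid_class = classify_hybrid(f),
    stringsAsFactors = FALSE
  )
}

#' Classify F_hybrid scores into backcross-generation classes
#'
#' Boundaries at 0.0625, 0.125 and 0.250 (expected 4th-, 3rd-,
#' 2nd-generation hybrid fractions).
#'
#' @param f numeric F_hybrid scores.
#' @return character vector: `none`, `gen4`, `gen3`, `gen2_or_more`.
#' @export
classify_hybrid <- function(f) {
  cls <- rep("none", length(f))
  cls[f >= 0.0625 & f < 0.125] <- "gen4"
  cls[f >= 0.125 & f <= 0.250] <- "gen3"
  cls[f > 0.250] <- "gen2_or_more"
  cls
}

#' End-to-end hybrid-index stage
#'
#' Convenience wrapper: estimates counted-allele frequencies in the wild
#' pool (per cluster when `cluster_id` is set), simulates `n_pure` pure
#' genotypes per cluster, computes Hamming distances over pigs + pure +
#' focal samples, ordinates, and projects.
#'
#' @param wild wild-group [genotype_matrix()]; supplies the cluster-level
#'   allele frequencies anchoring the pure end of the axis.
#' @param pigs pig-reference [genotype_matrix()] on the same marker map.
#' @param focal optional extra [genotype_matrix()] of samples to score
#'   (e.g. putative hybrids) that should not enter the frequency
#'   estimate; `NULL` scores the wild samples only.
#' @param n_pure simulated pure individuals per cluster (default 20).
#' @param axes_used ordination axes entering the projection (default 2).
#' @param max_axes axes retained in the ordination.
#' @param seed RNG seed for the pure-genotype simulation.
#' @return list: `scores` (per-sample data.frame from
#'   [project_f_hybrid()]), `ordination`, `samples`.
#' @export
hybrid_index_stage <- function(wild, pigs, focal = NULL, n_pure = 20,
                               axes_used = 2, max_axes = 10, seed = 1L) {
  if (!identical(wild$markers$locus_id, pigs$markers$locus_id))
    stop("hybrid_index_stage: wild and pig marker maps differ")
  clusters <- unique(wild$samples$cluster_id)
  clusters <- clusters[!is.na(clusters)]
  if (!length(clusters)) clusters <- "all"
  set.seed(seed)
  pure_list <- lapply(seq_along(clusters), function(ci) {
    cl <- clusters[ci]
    sub <- if (identical(cl, "all")) NULL else
      which(wild$samples$cluster_id == cl)
    p <- allele_b_frequency(wild, sample_subset = sub)
    p[is.na(p)] <- 0
    simulate_pure_genotypes(p, n = n_pure, markers = wild$markers,
                            prefix = paste0("pure_", cl))
  })
  extra <- if (is.null(focal)) list() else list(focal)
  combined <- do.call(bind_genotypes,
                      c(list(pigs, wild), extra, pure_list))
  dm <- hamming_distance_matrix(combined)
  ord <- pcoa_ordination(dm, max_axes = max_axes)
  scores <- project_f_hybrid(ord, combined$samples, axes_used = axes_used)
  list(scores = scores, ordination = ord, samples = combined$samples)
}

#' Row-bind genotype matrices sharing a marker map
#'
#' @param ... [genotype_matrix()] objects with identical marker maps.
#' @return a combined `genotype_matrix`.
#' @export
bind_genotypes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1) return(gs[[1]])
  m0 <- gs[[1]]$markers
  for (g in gs[-1]) {
    if (!identical(g$markers$locus_id, m0$locus_id))
      stop("bind_genotypes: marker maps differ")
  }
  d <- do.call(rbind, lapply(gs, function(g) g$dosage))
  s <- do.call(rbind, lapply(gs, function(g) as.data.frame(g$samples)))
  genotype_matrix(d, m0, sample_table(
    s$sample_id, s$group, s$location_id, s$longitude, s$latitude,
    s$cluster_id))
}

#' Pig-diagnostic alleles
#'
#' Loci carrying an allele that is rare in the wild pool (frequency below
#' `wild_max`, default 0.025) yet common in the pig pool (frequency above
#' `pig_min`, default 0.225). Both thresholds are applied to the same
#' allele.
#'
#' @param wild,pigs [genotype_matrix()] objects on a shared marker map.
#' @param wild_max,pig_min frequency thresholds.
#' @return data.frame: `locus_id`, `diagnostic_allele` ("a" or "b"),
#'   `wild_freq`, `pig_freq`.
#' @export
diagnostic_alleles <- function(wild, pigs, wild_max = 0.025,
                               pig_min = 0.225) {
  if (!identical(wild$markers$locus_id, pigs$markers$locus_id))
    stop("diagnostic_alleles: marker maps differ")
  pw <- suppressWarnings(allele_b_frequency(wild))
  pp <- suppressWarnings(allele_b_frequency(pigs))
  out <- data.frame(locus_id = character(), diagnostic_allele = character(),
                    wild_freq = numeric(), pig_freq = numeric(),
                    stringsAsFactors = FALSE)
  ok <- !is.na(pw) & !is.na(pp)
  # allele b rare in wild, common in pigs
  sel_b <- ok & pw < wild_max & pp > pig_min
  # allele a rare in wild, common in pigs
  sel_a <- ok & (1 - pw) < wild_max & (1 - pp) > pig_min
  rbind(
    data.frame(locus_id = wild$markers$locus_id[sel_b],
               diagnostic_allele = rep("b", sum(sel_b)),
               wild_freq = unname(pw[sel_b]),
               pig_freq = unname(pp[sel_b]),
               stringsAsFactors = FALSE),
    data.frame(locus_id = wild$markers$locus_id[sel_a],
               diagnostic_allele = rep("a", sum(sel_a)),
               wild_freq = unname(1 - pw[sel_a]),
               pig_freq = unname(1 - pp[sel_a]),
               stringsAsFactors = FALSE)
  )
}

#' Genomic clustering profile of carried diagnostic alleles
#'
#' For one sample: the fraction of diagnostic loci at which it carries at
#' least one diagnostic allele, the maximum number of carried diagnostic
#' loci in any sliding genomic window (default 10 Mb), and a permutation
#' p-value for that clustering score. The null conditions on the sample's
#' carrier count and permutes which diagnostic loci are carried, so the
#' test asks about spatial arrangement, not introgression load.
#'
#' @param g a [genotype_matrix()] containing the sample.
#' @param sample_id the focal sample.
#' @param das output of [diagnostic_alleles()].
#' @param window_mb sliding-window width in megabases (default 10).
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed RNG seed.
#' @return list: `carrier_fraction`, `cluster_score`, `p_value`,
#'   `n_carried`.
#' @export
diagnostic_allele_profile <- function(g, sample_id, das, window_mb = 10,
                                      n_perm = 1000, seed = 1L) {
  if (nrow(das) == 0) stop("diagnostic_allele_profile: empty allele set")
  if (n_perm < 100)
    warning("diagnostic_allele_profile: n_perm < 100 is unreliable")
  si <- match(sample_id, g$samples$sample_id)
  if (is.na(si)) stop("unknown sample: ", sample_id)
  li <- match(das$locus_id, g$markers$locus_id)
  if (anyNA(li)) stop("diagnostic loci missing from marker map")
  d <- g$dosage[si, li]
  carried <- ifelse(das$diagnostic_allele == "b", d >= 1, d <= 1)
  carried[is.na(d)] <- FALSE
  n_car <- sum(carried)
  n_das <- length(carried)
  chrom <- g$markers$chromosome[li]
  pos <- g$markers$position_bp[li]
  win <- window_mb * 1e6

  score <- function(is_carried) {
    best <- 0L
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      p <- pos[sel]
      c_ <- is_carried[sel]
      o <- order(p)
      p <- p[o]; c_ <- c_[o]
      cs <- cumsum(c_)
      # windows anchored at each diagnostic locus
      hi <- findInterval(p + win - 1, p)
      cnt <- cs[hi] - cs + c_
      best <- max(best, max(cnt))
    }
    best
  }
  obs <- score(carried)
  if (n_car == 0) {
    return(list(carrier_fraction = 0, cluster_score = 0, p_value = 1,
                n_carried = 0L))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- logical(n_das)
    perm[sample.int(n_das, n_car)] <- TRUE
    if (score(perm) >= obs) exceed <- exceed + 1L
  }
  list(carrier_fraction = n_car / n_das,
       cluster_score = obs,
       p_value = (1 + exceed) / (1 + n_perm),
       n_carried = n_car)
}
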