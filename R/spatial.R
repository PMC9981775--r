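#' Downsample to at most `max_n` individuals per location
#'
#' Ordinations are biased by uneven sampling, so structure analyses run on
#' at most five (by default) randomly chosen individuals per sampling
#' location; the draw is seeded and reproducible.
#'
#' @param s a [sample_table()].
#' @param max_n maximum individuals per location (default 5).
#' @param seed RNG seed.
#' @return character vector of retained sample ids.
#' @export
downsample_per_location <- function(s, max_n = 5, seed = 1L) {
  set.seed(seed)
  keep <- character()
  for (loc in sort(unique(s$location_id))) {
    ids <- s$sample_id[!is.na(s$location_id) & s$location_id == loc]
    if (length(ids) > max_n) ids <- sort(sample(ids, max_n))
    keep <- c(keep, ids)
  }
  keep <- c(keep, s$sample_id[is.na(s$location_id)])
  keep[order(match(keep, s$sample_id))]
}

#' Exclude inbred and hybrid individuals
#'
#' Structure analyses exclude individuals with F_ROH or F_hybrid above a
#' threshold (default 0.0625) so recent inbreeding and pig introgression
#' do not confound the spatial signal.
#'
#' @param hybrid data.frame with `sample_id`, `f_hybrid`.
#' @param inbreeding data.frame with `sample_id`, `f_roh`.
#' @param threshold exclusion threshold applied to both scores.
#' @return character vector of retained sample ids (those present in both
#'   result sets and below both thresholds).
#' @export
exclude_inbred_and_hybrid <- function(hybrid, inbreeding,
                                      threshold = 0.0625) {
  ids <- intersect(hybrid$sample_id, inbreeding$sample_id)
  fh <- hybrid$f_hybrid[match(ids, hybrid$sample_id)]
  fr <- inbreeding$f_roh[match(ids, inbreeding$sample_id)]
  ids[fh <= threshold & fr <= threshold]
}

#' Great-circle distance matrix (km)
#'
#' Haversine distances between sample coordinates (R = 6371 km).
#'
#' @param s a [sample_table()] with longitude/latitude set.
#' @return symmetric matrix of distances in kilometres.
#' @export
geographic_distance_matrix <- function(s) {
  bad <- s$sample_id[is.na(s$longitude) | is.na(s$latitude)]
  if (length(bad))
    stop("geographic_distance_matrix: missing coordinates for: ",
         paste(bad, collapse = ", "))
  xy <- cbind(s$longitude, s$latitude)
  n <- nrow(xy)
  dm <- matrix(0, n, n, dimnames = list(s$sample_id, s$sample_id))
  for (i in seq_len(n)) {
    dm[i, ] <- geosphere::distHaversine(xy[i, ], xy, r = 6371000) / 1000
  }
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dm
}

#' Collapse an individual-level distance matrix to location level
#'
#' Entry (A, B) is the mean distance over all pairs with one individual in
#' location A and one in B; the diagonal is zero. Used for
#' population-level Mantel tests, which reduce the autocorrelation of
#' individual-level comparisons.
#'
#' @param d individual-level symmetric distance matrix (dimnames =
#'   sample ids).
#' @param s a [sample_table()] covering the matrix ids.
#' @return symmetric matrix over locations.
#' @export
location_mean_distance <- function(d, s) {
  loc <- s$location_id[match(rownames(d), s$sample_id)]
  if (anyNA(loc))
    stop("location_mean_distance: samples without location_id")
  locs <- sort(unique(loc))
  nl <- length(locs)
  out <- matrix(0, nl, nl, dimnames = list(locs, locs))
  for (a in seq_len(nl)) {
    for (b in seq_len(nl)) {
      if (a >= b) next
      out[a, b] <- out[b, a] <-
        mean(d[loc == locs[a], loc == locs[b], drop = FALSE])
    }
  }
  out
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation r of the off-diagonal upper triangles of two
#' distance matrices, with significance from joint row/column
#' permutations of one matrix. The p-value uses the add-one convention
#' p = (1 + #extreme) / (1 + n_perm) and is two-sided by default. With
#' `exact = TRUE` (or n small enough) all n! permutations are enumerated.
#'
#' @param d_gen,d_geo symmetric matrices of equal size and ordering.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param two_sided two-sided test on |r| (default) or one-sided
#'   (greater).
#' @param exact enumerate all permutations (n <= 8 recommended).
#' @return list of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = 1L,
                        two_sided = TRUE, exact = FALSE) {
  d_gen <- as.matrix(d_gen)
  d_geo <- as.matrix(d_geo)
  n <- nrow(d_gen)
  if (n < 3) stop("mantel_test: need at least 3 units")
  if (!all(dim(d_gen) == dim(d_geo)))
    stop("mantel_test: matrix sizes differ")
  ut <- upper.tri(d_gen)
  r_obs <- stats::cor(d_gen[ut], d_geo[ut])
  stat <- function(perm) {
    dp <- d_gen[perm, perm]
    stats::cor(dp[ut], d_geo[ut])
  }
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, numeric(1))
    # the identity permutation is part of the reference set
    extreme <- if (two_sided) sum(abs(rs) >= abs(r_obs) - 1e-12) else
      sum(rs >= r_obs - 1e-12)
    res <- list(r = r_obs, p_value = extreme / length(perms),
                n_permutations = length(perms))
  } else {
    set.seed(seed)
    extreme <- 0L
    for (b in seq_len(n_perm)) {
      rp <- stat(sample.int(n))
      hit <- if (two_sided) abs(rp) >= abs(r_obs) - 1e-12 else
        rp >= r_obs - 1e-12
      if (hit) extreme <- extreme + 1L
    }
    res <- list(r = r_obs, p_value = (1 + extreme) / (1 + n_perm),
                n_permutations = n_perm)
  }
  class(res) <- "mantel_result"
  res
}

all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Spearman correlation of ordination axes with geography
#'
#' Mean PCoA axis scores per sampling location are rank-correlated with
#' location longitude and latitude (all four axis/coordinate pairs
#' reported). Aggregating to location level reduces spatial
#' autocorrelation among individuals of the same site. Degenerate
#' (constant) axes yield `NA` with a flag.
#'
#' @param ord a [pcoa_ordination()] result.
#' @param s a [sample_table()] aligned with ordination rows.
#' @return data.frame: `axis`, `geo_variable`, `spearman_rho`, `p_value`,
#'   `degenerate`.
#' @export
axis_geography_correlation <- function(ord, s) {
  co <- ord$coordinates
  loc <- s$location_id
  if (length(unique(loc[!is.na(loc)])) < 3)
    stop("axis_geography_correlation: need at least 3 locations")
  agg <- stats::aggregate(
    cbind(axis1 = co[, 1], axis2 = co[, min(2, ncol(co))],
          longitude = s$longitude, latitude = s$latitude),
    by = list(location_id = loc), FUN = mean)
  out <- list()
  k <- 0
  for (ax in c("axis1", "axis2")) {
    for (gv in c("longitude", "latitude")) {
      x <- agg[[ax]]
      y <- agg[[gv]]
      degen <- stats::sd(x) == 0 || stats::sd(y) == 0
      if (degen) {
        rho <- NA_real_; pv <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman"))
        rho <- unname(ct$estimate); pv <- ct$p.value
      }
      k <- k + 1
      out[[k]] <- data.frame(
        axis = ax, geo_variable = gv, spearman_rho = rho, p_value = pv,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Multilocus observed heterozygosity
#'
#' Per sample: heterozygous loci / non-missing loci. Decile class labels
#' (equal-count intervals) are attached for mapping.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame: `sample_id`, `mlh`, `n_typed`, `decile`.
#' @export
mlh <- function(g) {
  het <- rowSums(g$dosage == 1L, na.rm = TRUE)
  typed <- rowSums(!is.na(g$dosage))
  if (any(typed == 0))
    warning("mlh: sample(s) with no typed loci: ",
            paste(g$samples$sample_id[typed == 0], collapse = ", "))
  h <- ifelse(typed > 0, het / typed, NA_real_)
  dec <- rep(NA_integer_, length(h))
  ok <- !is.na(h)
  if (sum(ok) >= 10) {
    # equal-count classes; ties split by sample order
    dec[ok] <- as.integer(ceiling(
      rank(h[ok], ties.method = "first") * 10 / sum(ok)))
  }
  data.frame(sample_id = g$samples$sample_id, mlh = h, n_typed = typed,
             decile = dec, stringsAsFactors = FALSE)
}

#' Linear model of multilocus heterozygosity
#'
#' Ordinary least squares of MLH on longitude, F_hybrid and F_ROH
#' (latitude is screened in a separate univariate model, mirroring a
#' design where it showed no effect). Collinear designs are rejected via
#' a condition-number guard.
#'
#' @param data data.frame with columns `mlh`, `longitude`, `latitude`,
#'   `f_hybrid`, `f_roh` (complete cases used).
#' @return list: `coefficients` (term, estimate, t_value, p_value),
#'   `F_statistic`, `r2_adj`, `df_residual`, `latitude_p` (univariate
#'   screen), `model` (the lm fit).
#' @export
mlh_linear_model <- function(data) {
  d <- data[stats::complete.cases(
    data[, c("mlh", "longitude", "f_hybrid", "f_roh")]), ]
  X <- cbind(1, d$longitude, d$f_hybrid, d$f_roh)
  if (kappa(X, exact = TRUE) > 1e10)
    stop("mlh_linear_model: design matrix is (near-)collinear")
  fit <- stats::lm(mlh ~ longitude + f_hybrid + f_roh, data = d)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_error", "t_value", "p_value")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  lat_p <- NA_real_
  if ("latitude" %in% names(d) && !all(is.na(d$latitude))) {
    lat_fit <- summary(stats::lm(mlh ~ latitude, data = d))
    lat_p <- lat_fit$coefficients["latitude", "Pr(>|t|)"]
  }
  list(coefficients = co,
       F_statistic = unname(sm$fstatistic[1]),
       r2_adj = sm$adj.r.squared,
       df_residual = fit$df.residual,
       latitude_p = lat_p,
       model = fit)
}

#' Select alleles typical of a focal region
#'
#' For each locus the allele that is minor at full-panel scale is
#' identified; the locus is selected when that allele's frequency within
#' the focal region's samples exceeds `freq_min` (default 0.5, i.e. the
#' panel-minor allele is locally major). Monomorphic panel loci are
#' skipped.
#'
#' @param g a [genotype_matrix()].
#' @param s a [sample_table()] covering the samples of `g`.
#' @param focal character vector of focal `location_id`s.
#' @param freq_min within-region frequency threshold.
#' @return data.frame: `locus_id`, `allele` ("a"/"b"), `panel_freq`,
#'   `focal_freq`.
#' @export
select_regional_alleles <- function(g, s, focal, freq_min = 0.5) {
  if (!length(focal)) stop("select_regional_alleles: empty focal set")
  loc <- s$location_id[match(g$samples$sample_id, s$sample_id)]
  in_focal <- which(!is.na(loc) & loc %in% focal)
  if (!length(in_focal))
    stop("select_regional_alleles: no samples in focal region")
  p_all <- suppressWarnings(allele_b_frequency(g))
  p_foc <- suppressWarnings(allele_b_frequency(g, sample_subset = in_focal))
  ok <- !is.na(p_all) & !is.na(p_foc) & p_all > 0 & p_all < 1
  # panel-minor allele: b if p_all < 0.5, else a
  minor_is_b <- p_all < 0.5
  minor_focal <- ifelse(minor_is_b, p_foc, 1 - p_foc)
  sel <- ok & p_all != 0.5 & minor_focal > freq_min
  data.frame(
    locus_id = g$markers$locus_id[sel],
    allele = ifelse(minor_is_b[sel], "b", "a"),
    panel_freq = ifelse(minor_is_b[sel], p_all[sel], 1 - p_all[sel]),
    focal_freq = minor_focal[sel],
    stringsAsFactors = FALSE
  )
}

#' Mean frequency of region-typical alleles per location
#'
#' @param g a [genotype_matrix()].
#' @param s a [sample_table()] covering the samples of `g`.
#' @param selection output of [select_regional_alleles()].
#' @return data.frame: `location_id`, `mean_freq`, `n_samples`,
#'   `longitude`, `latitude`; locations with no typed selected loci are
#'   flagged `NA`.
#' @export
mean_regional_frequency <- function(g, s, selection) {
  if (nrow(selection) == 0)
    stop("mean_regional_frequency: empty selection")
  li <- match(selection$locus_id, g$markers$locus_id)
  loc <- s$location_id[match(g$samples$sample_id, s$sample_id)]
  locs <- sort(unique(loc[!is.na(loc)]))
  out <- lapply(locs, function(L) {
    si <- which(!is.na(loc) & loc == L)
    p <- suppressWarnings(allele_b_frequency(g, sample_subset = si))[li]
    p <- ifelse(selection$allele == "b", p, 1 - p)
    data.frame(
      location_id = L,
      mean_freq = if (all(is.na(p))) NA_real_ else mean(p, na.rm = TRUE),
      n_samples = length(si),
      longitude = mean(s$longitude[match(g$samples$sample_id[si],
                                         s$sample_id)], na.rm = TRUE),
      latitude = mean(s$latitude[match(g$samples$sample_id[si],
                                       s$sample_id)], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
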