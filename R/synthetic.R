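#' Population model for synthetic genotype data
#'
#' Describes a set of diverged populations placed on a geographic grid:
#' ancestral allele frequencies drawn from `ancestral_law` (default
#' Uniform(0.05, 0.95)), per-population divergence F (Balding-Nichols),
#' and an optional allele-frequency cline across the population
#' locations. Two populations drawn independently at divergence F have
#' expected pairwise FST close to F.
#'
#' @param n_populations number of populations.
#' @param fst divergence parameter, scalar or per population, in (0, 1)
#'   (0 allowed: exact copy of the ancestral frequency).
#' @param n_loci number of loci.
#' @param locations data.frame with `longitude`, `latitude` (one row per
#'   population); defaults to a west-east transect across Europe.
#' @param cline optional list(direction = c(dx, dy), strength) shifting
#'   frequencies along the direction via a logistic transform.
#' @param ancestral_law function(n) drawing ancestral frequencies.
#' @return a list of class `population_model`.
#' @export
population_model <- function(n_populations, fst = 0.05, n_loci = 1000,
                             locations = NULL, cline = NULL,
                             ancestral_law = function(n)
                               stats::runif(n, 0.05, 0.95)) {
  fst <- rep(fst, length.out = n_populations)
  if (any(fst < 0 | fst >= 1))
    stop("population_model: fst must lie in [0, 1)")
  if (n_loci < 1) stop("population_model: n_loci must be >= 1")
  if (is.null(locations)) {
    locations <- data.frame(
      longitude = seq(-8, 25, length.out = n_populations),
      latitude = rep(c(42, 48, 52), length.out = n_populations))
  }
  if (nrow(locations) != n_populations)
    stop("population_model: need one location per population")
  m <- list(n_populations = n_populations, fst = fst,
            n_loci = as.integer(n_loci), locations = locations,
            cline = cline, ancestral_law = ancestral_law)
  class(m) <- "population_model"
  m
}

#' Balding-Nichols population allele frequencies
#'
#' Ancestral frequency p per locus from the model's ancestral law;
#' population k's frequency drawn from
#' Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k), so that
#' E\[freq\] = p and Var\[freq\] = F_k p (1 - p). F = 0 copies the
#' ancestral frequency exactly.
#'
#' @param model a [population_model()].
#' @param seed RNG seed.
#' @return list: `ancestral` (length n_loci), `freqs` (n_populations x
#'   n_loci matrix).
#' @export
balding_nichols_freqs <- function(model, seed = 1L) {
  set.seed(seed)
  p <- model$ancestral_law(model$n_loci)
  freqs <- matrix(NA_real_, model$n_populations, model$n_loci)
  for (k in seq_len(model$n_populations)) {
    F <- model$fst[k]
    if (F == 0) {
      freqs[k, ] <- p
    } else {
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      freqs[k, ] <- stats::rbeta(model$n_loci, a, b)
    }
  }
  if (!is.null(model$cline)) freqs <- apply_cline(freqs, model)
  list(ancestral = p, freqs = freqs)
}

#' Shift population frequencies along a geographic cline
#'
#' Projects each population's location onto the cline direction,
#' standardises the projections, and shifts every locus's logit frequency
#' by `strength` times the standardised projection. Strength 0 leaves
#' frequencies unchanged; frequencies stay inside (0, 1).
#'
#' @param freqs n_populations x n_loci frequency matrix.
#' @param model a [population_model()] with `cline` set.
#' @return adjusted frequency matrix.
#' @export
apply_cline <- function(freqs, model) {
  cl <- model$cline
  if (is.null(cl) || cl$strength == 0) return(freqs)
  v <- cl$direction / sqrt(sum(cl$direction^2))
  proj <- as.numeric(as.matrix(
    model$locations[, c("longitude", "latitude")]) %*% v)
  s <- as.numeric(scale(proj))
  if (anyNA(s)) s <- rep(0, length(proj))  # single location
  eps <- 1e-6
  f <- pmin(pmax(freqs, eps), 1 - eps)
  stats::plogis(stats::qlogis(f) + cl$strength * s)
}

#' Sample Hardy-Weinberg genotypes from population frequencies
#'
#' Dosage ~ Binomial(2, freq) per individual and locus; missingness is
#' applied afterwards at the declared rate. Samples are labelled by
#' population with locations from the model.
#'
#' @param freqs n_populations x n_loci frequency matrix (a single
#'   population may be given as a vector).
#' @param n_per_pop individuals per population (scalar or vector).
#' @param model optional [population_model()] supplying locations.
#' @param missing_rate fraction of calls set to missing (default 0).
#' @param seed RNG seed.
#' @param group sample group label (default `"wild"`).
#' @param prefix sample-id prefix.
#' @param markers optional [marker_map()]; generic map built if omitted.
#' @return a [genotype_matrix()]; `location_id` = "pop<k>",
#'   `cluster_id` likewise.
#' @export
sample_genotypes <- function(freqs, n_per_pop, model = NULL,
                             missing_rate = 0, seed = 1L,
                             group = "wild", prefix = "S",
                             markers = NULL) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  if (any(freqs < 0 | freqs > 1))
    stop("sample_genotypes: frequencies must lie in [0, 1]")
  npop <- nrow(freqs)
  nl <- ncol(freqs)
  n_per_pop <- rep(n_per_pop, length.out = npop)
  set.seed(seed)
  rows <- list()
  ids <- loc <- character()
  lon <- lat <- numeric()
  for (k in seq_len(npop)) {
    n <- n_per_pop[k]
    d <- matrix(stats::rbinom(n * nl, 2, rep(freqs[k, ], each = n)),
                nrow = n)
    rows[[k]] <- d
    ids <- c(ids, sprintf("%s%d_%03d", prefix, k, seq_len(n)))
    loc <- c(loc, rep(paste0("pop", k), n))
    if (!is.null(model)) {
      lon <- c(lon, rep(model$locations$longitude[k], n))
      lat <- c(lat, rep(model$locations$latitude[k], n))
    }
  }
  d <- do.call(rbind, rows)
  if (missing_rate > 0) {
    d[stats::runif(length(d)) < missing_rate] <- NA_integer_
  }
  if (is.null(markers))
    markers <- marker_map(paste0("L", seq_len(nl)), "1", seq_len(nl))
  sm <- sample_table(
    ids, group = group, location_id = loc,
    longitude = if (length(lon)) lon else NA_real_,
    latitude = if (length(lat)) lat else NA_real_,
    cluster_id = loc)
  genotype_matrix(d, markers, sm)
}
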