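#' Hybrid-index recovery experiment on synthetic pools
#'
#' Simulates the canonical validation design for the PCoA-projection
#' hybrid index: a wild and a pig pool drawn Balding-Nichols around a
#' shared ancestral frequency spectrum (pairwise FST approximately
#' `fst`), gene-dropped backcross cohorts of depth 1-4 plus held-out
#' pure wild and pure pig cohorts, and the full hybrid-index stage run
#' against them (cluster-level frequency estimation, `n_pure` simulated
#' pure genotypes, Hamming distances, ordination, polar-axis
#' projection). Loci with wild-pool MAF at or below `min_maf` are removed
#' before scoring, mimicking the QC chain.
#'
#' Expected cohort means are 2^-depth for backcrosses (0.5, 0.25, 0.125,
#' 0.0625), 0 for wild and 1 for pigs; the McVean linearity of the
#' estimator is summarised by the slope of mean score on nominal
#' ancestry.
#'
#' @param seed RNG seed driving every stochastic step.
#' @param n_wild,n_pig_ref wild and pig reference pool sizes.
#' @param n_per_cohort gene-dropped offspring per backcross depth.
#' @param marker_spacing_bp marker spacing over the 18-autosome genome
#'   (default 440 kb, about 5,100 loci).
#' @param fst Balding-Nichols divergence of each pool from the shared
#'   ancestral spectrum.
#' @param min_maf wild-pool MAF floor applied before scoring.
#' @param n_pure,axes_used hybrid-stage settings.
#' @return list: `cohorts` (data.frame with cohort, alpha, mean and sd of
#'   f_hybrid, mean true ancestry, n), `slope` (fitted slope of mean
#'   f_hybrid on alpha), `n_loci` (post-filter locus count), `scores`.
#' @export
benchmark_hybrid_recovery <- function(seed = 1L, n_wild = 300,
                                      n_pig_ref = 60, n_per_cohort = 50,
                                      marker_spacing_bp = 44e4,
                                      fst = 0.15, min_maf = 0.025,
                                      n_pure = 20, axes_used = 2) {
  gmap <- genetic_map()
  mk <- make_marker_map(gmap, spacing_bp = marker_spacing_bp)
  nl <- nrow(mk)
  set.seed(seed)
  anc <- stats::runif(nl, 0.05, 0.95)
  pw <- stats::rbeta(nl, anc * (1 - fst) / fst,
                     (1 - anc) * (1 - fst) / fst)
  pp <- stats::rbeta(nl, anc * (1 - fst) / fst,
                     (1 - anc) * (1 - fst) / fst)
  wild <- sample_genotypes(pw, n_wild, seed = seed + 1, prefix = "W",
                           markers = mk)
  pigs <- sample_genotypes(pp, n_pig_ref, seed = seed + 2,
                           group = "pig_reference", prefix = "P",
                           markers = mk)
  ff <- list(wild = pw, pig = pp)
  cohorts <- list()
  truth <- list()
  for (g in 1:4) {
    gd <- gene_drop(pedigree_backcross(g), gmap, ff, markers = mk,
                    n_rep = n_per_cohort, seed = seed + 10 + g)
    gd$genotypes$samples$sample_id <-
      paste0("BX", g, "_", gd$genotypes$samples$sample_id)
    gd$genotypes$samples$group <- "wild"
    rownames(gd$genotypes$dosage) <- gd$genotypes$samples$sample_id
    cohorts[[paste0("depth", g)]] <- gd$genotypes
    truth[[paste0("depth", g)]] <- gd$truth$pig_ancestry
  }
  cohorts$wild0 <- sample_genotypes(pw, n_per_cohort, seed = seed + 20,
                                    prefix = "W0", markers = mk)
  cohorts$pig1 <- sample_genotypes(pp, n_per_cohort, seed = seed + 21,
                                   prefix = "P1", markers = mk)
  truth$wild0 <- rep(0, n_per_cohort)
  truth$pig1 <- rep(1, n_per_cohort)

  # QC-style MAF filter defined on the wild pool
  maf <- suppressWarnings(minor_allele_frequency(wild))
  keep <- which(!is.na(maf) & maf > min_maf)
  wild <- subset_genotypes(wild, loci = keep)
  pigs <- subset_genotypes(pigs, loci = keep)
  cohorts <- lapply(cohorts, subset_genotypes, loci = keep)

  focal <- do.call(bind_genotypes, unname(cohorts))
  hs <- hybrid_index_stage(wild, pigs, focal = focal, n_pure = n_pure,
                           axes_used = axes_used, seed = seed + 30)
  sc <- hs$scores
  alpha <- c(depth1 = 0.5, depth2 = 0.25, depth3 = 0.125,
             depth4 = 0.0625, wild0 = 0, pig1 = 1)
  tab <- do.call(rbind, lapply(names(cohorts), function(nm) {
    ids <- cohorts[[nm]]$samples$sample_id
    f <- sc$f_hybrid[match(ids, sc$sample_id)]
    data.frame(cohort = nm, alpha = unname(alpha[nm]),
               mean_f_hybrid = mean(f), sd_f_hybrid = stats::sd(f),
               mean_true_ancestry = mean(truth[[nm]]), n = length(f),
               stringsAsFactors = FALSE)
  }))
  slope <- unname(stats::coef(
    stats::lm(mean_f_hybrid ~ alpha, data = tab))[2])
  list(cohorts = tab, slope = slope, n_loci = length(keep),
       scores = sc)
}

#' Pedigree autozygosity experiment
#'
#' Gene-drops offspring of the three inbred-mating classes over the full
#' 18-autosome genome and summarises the true genome IBD fraction per
#' class against the path-counting expectation (1/8 for half-sibling
#' matings, 1/16 for full cousins, 1/32 for half cousins).
#'
#' @param seed RNG seed.
#' @param n_rep offspring per relationship class.
#' @param marker_spacing_bp marker spacing (markers only affect the
#'   genotype output, not the IBD truth; a sparse map keeps this fast).
#' @return data.frame: `class`, `expected_f`, `mean_ibd`, `se`, `n`.
#' @export
benchmark_pedigree_autozygosity <- function(seed = 1L, n_rep = 200,
                                            marker_spacing_bp = 5e6) {
  gmap <- genetic_map()
  mk <- make_marker_map(gmap, spacing_bp = marker_spacing_bp)
  ff <- list(wild = rep(0.5, nrow(mk)))
  peds <- list(half_sib = pedigree_half_sib(),
               full_cousin = pedigree_full_cousin(),
               half_cousin = pedigree_half_cousin())
  expected <- c(half_sib = 1 / 8, full_cousin = 1 / 16,
                half_cousin = 1 / 32)
  out <- lapply(names(peds), function(nm) {
    gd <- gene_drop(peds[[nm]], gmap, ff, markers = mk, n_rep = n_rep,
                    seed = seed + match(nm, names(peds)))
    x <- gd$truth$ibd_fraction
    data.frame(class = nm, expected_f = unname(expected[nm]),
               mean_ibd = mean(x), se = stats::sd(x) / sqrt(length(x)),
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
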