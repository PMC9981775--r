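#' Write a self-contained synthetic benchmark suite
#'
#' Generates, deterministically from one seed, the fixture datasets every
#' pipeline stage needs: (a) a four-cluster continental panel with a
#' west-east allele-frequency cline; (b) a pig-reference pool diverged
#' from the wild pool; (c) pig x wild backcross cohorts of depth 1-4;
#' (d) inbred cohorts (half-sib, full-cousin, half-cousin matings); and
#' (e) truth tables (true pig-ancestry fractions, true IBD fractions and
#' tracts). Genotypes are written as PLINK PED/MAP, metadata as CSV,
#' truth as TSV.
#'
#' The panel and cohorts share one marker map (default: 4 chromosomes of
#' the pig-like genome at 1 marker / 100 kb) so hybrids and inbred
#' cohorts can be analysed against the panel.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed; the same seed reproduces byte-identical files.
#' @param n_chromosomes chromosomes of the default [genetic_map()] used.
#' @param marker_spacing_bp marker spacing (default 100 kb, dense enough
#'   for the ROH criteria).
#' @param n_per_location panel individuals per sampling location.
#' @param n_locations_per_cluster sampling locations per genetic cluster.
#' @param n_hybrids,n_inbred cohort sizes per depth / relationship class.
#' @param n_pigs pig-reference pool size.
#' @param missing_rate panel missingness rate.
#' @return invisibly, the list of written file paths.
#' @export
make_benchmark_suite <- function(dir, seed = 1L, n_chromosomes = 4,
                                 marker_spacing_bp = 1e5,
                                 n_per_location = 6,
                                 n_locations_per_cluster = 3,
                                 n_hybrids = 20, n_inbred = 20,
                                 n_pigs = 30, missing_rate = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gmap <- genetic_map(n_chromosomes = n_chromosomes)
  markers <- make_marker_map(gmap, spacing_bp = marker_spacing_bp)
  nl <- nrow(markers)
  set.seed(seed)

  # --- (a) continental panel: 4 clusters x locations, with cline
  n_clusters <- 4
  n_loc <- n_clusters * n_locations_per_cluster
  cl_lon <- c(-6, 2, 12, 22)   # Iberia-like .. eastern cluster
  cl_lat <- c(40, 46, 43, 50)
  loc <- data.frame(
    longitude = rep(cl_lon, each = n_locations_per_cluster) +
      stats::runif(n_loc, -1.5, 1.5),
    latitude = rep(cl_lat, each = n_locations_per_cluster) +
      stats::runif(n_loc, -1.5, 1.5))
  model <- population_model(
    n_populations = n_loc, fst = 0.05, n_loci = nl, locations = loc,
    cline = list(direction = c(1, 0), strength = 0.8))
  bn <- balding_nichols_freqs(model, seed = seed + 1)
  panel <- sample_genotypes(bn$freqs, n_per_location, model = model,
                            missing_rate = missing_rate,
                            seed = seed + 2, prefix = "WB",
                            markers = markers)
  cluster_of_loc <- rep(paste0("cluster", seq_len(n_clusters)),
                        each = n_locations_per_cluster)
  panel$samples$cluster_id <- cluster_of_loc[
    as.integer(sub("pop", "", panel$samples$location_id))]

  # --- (b) pig reference pool: diverged from the shared ancestral
  pig_model <- population_model(n_populations = 1, fst = 0.15,
                                n_loci = nl,
                                locations = data.frame(longitude = 0,
                                                       latitude = 45))
  set.seed(seed + 3)
  F <- 0.15
  pig_freq <- stats::rbeta(nl, bn$ancestral * (1 - F) / F,
                           (1 - bn$ancestral) * (1 - F) / F)
  pigs <- sample_genotypes(pig_freq, n_pigs, seed = seed + 4,
                           group = "pig_reference", prefix = "PIG",
                           markers = markers)

  # wild-side founder frequencies for pedigrees: the ancestral pool
  founder_freqs <- list(wild = bn$ancestral, pig = pig_freq)

  # --- (c) hybrid cohorts depth 1-4
  hybrids <- list(); htruth <- list()
  for (g in 1:4) {
    gd <- gene_drop(pedigree_backcross(g), gmap, founder_freqs,
                    markers = markers, n_rep = n_hybrids,
                    seed = seed + 10 + g)
    gd$genotypes$samples$sample_id <-
      paste0("BX", g, "_", gd$genotypes$samples$sample_id)
    gd$truth$sample_id <- paste0("BX", g, "_", gd$truth$sample_id)
    gd$truth$cohort <- paste0("backcross_depth", g)
    rownames(gd$genotypes$dosage) <- gd$genotypes$samples$sample_id
    hybrids[[g]] <- gd$genotypes
    htruth[[g]] <- gd$truth
  }

  # --- (d) inbred cohorts
  peds <- list(half_sib = pedigree_half_sib(),
               full_cousin = pedigree_full_cousin(),
               half_cousin = pedigree_half_cousin())
  inbred <- list(); itruth <- list(); itracts <- list()
  for (k in seq_along(peds)) {
    gd <- gene_drop(peds[[k]], gmap, founder_freqs, markers = markers,
                    n_rep = n_inbred, seed = seed + 20 + k)
    pre <- toupper(substr(names(peds)[k], 1, 2))
    new_ids <- paste0(names(peds)[k], "_", gd$genotypes$samples$sample_id)
    gd$ibd_tracts$sample_id <- paste0(names(peds)[k], "_",
                                      gd$ibd_tracts$sample_id)
    gd$truth$sample_id <- new_ids
    gd$truth$cohort <- names(peds)[k]
    gd$genotypes$samples$sample_id <- new_ids
    rownames(gd$genotypes$dosage) <- new_ids
    inbred[[k]] <- gd$genotypes
    itruth[[k]] <- gd$truth
    itracts[[k]] <- gd$ibd_tracts
  }

  paths <- c(
    panel_ped = file.path(dir, "panel.ped"),
    panel_map = file.path(dir, "panel.map"),
    panel_meta = file.path(dir, "panel_samples.csv"),
    pigs_ped = file.path(dir, "pigs.ped"),
    pigs_map = file.path(dir, "pigs.map"),
    hybrids_ped = file.path(dir, "hybrids.ped"),
    hybrids_map = file.path(dir, "hybrids.map"),
    inbred_ped = file.path(dir, "inbred.ped"),
    inbred_map = file.path(dir, "inbred.map"),
    truth_ancestry = file.path(dir, "truth_ancestry.tsv"),
    truth_ibd_tracts = file.path(dir, "truth_ibd_tracts.tsv"))

  write_ped_map(panel, paths["panel_ped"], paths["panel_map"])
  utils::write.csv(as.data.frame(panel$samples), paths["panel_meta"],
                   row.names = FALSE, quote = FALSE)
  write_ped_map(pigs, paths["pigs_ped"], paths["pigs_map"])
  write_ped_map(do.call(bind_genotypes, hybrids),
                paths["hybrids_ped"], paths["hybrids_map"])
  write_ped_map(do.call(bind_genotypes, inbred),
                paths["inbred_ped"], paths["inbred_map"])
  truth <- rbind(do.call(rbind, htruth), do.call(rbind, itruth))
  utils::write.table(truth, paths["truth_ancestry"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, itracts), paths["truth_ibd_tracts"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(as.list(paths))
}
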