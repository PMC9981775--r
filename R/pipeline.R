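#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' blocks `paths` (genotypes_ped/map, pigs_ped/map, metadata, optional
#' gene_intervals, output_dir), `qc` ([qc_config()] fields), `roh`
#' ([roh_config()] fields), `hybrid` (n_pure, axes_used), `spatial`
#' (n_perm, grid_step, max_per_location, exclusion_threshold,
#' ld_r2_structure, optional focal_regions), and `seeds` — one explicit
#' integer per stochastic stage (`pure`, `downsample`, `mantel`).
#' Validation fails before any computation if a referenced file or a
#' required seed is missing.
#'
#' @param config path to a YAML file, or a list.
#' @return the validated configuration list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need_paths <- c("genotypes_ped", "genotypes_map", "pigs_ped",
                  "pigs_map", "metadata", "output_dir")
  miss <- setdiff(need_paths, names(config$paths))
  if (length(miss))
    stop("pipeline config: missing paths: ", paste(miss, collapse = ", "))
  for (p in setdiff(need_paths, "output_dir")) {
    if (!file.exists(config$paths[[p]]))
      stop("pipeline config: file not found: ", config$paths[[p]])
  }
  need_seeds <- c("pure", "downsample", "mantel")
  miss <- setdiff(need_seeds, names(config$seeds))
  if (length(miss))
    stop("pipeline config: every stochastic stage needs a seed; missing: ",
         paste(miss, collapse = ", "))
  config$qc <- do.call(qc_config, as.list(config$qc))
  config$roh <- do.call(roh_config, as.list(config$roh))
  hy <- config$hybrid
  config$hybrid <- list(
    n_pure = if (is.null(hy$n_pure)) 20 else hy$n_pure,
    axes_used = if (is.null(hy$axes_used)) 2 else hy$axes_used)
  sp <- config$spatial
  config$spatial <- list(
    n_perm = if (is.null(sp$n_perm)) 499 else sp$n_perm,
    grid_step = if (is.null(sp$grid_step)) 0.5 else sp$grid_step,
    max_per_location = if (is.null(sp$max_per_location)) 5 else
      sp$max_per_location,
    exclusion_threshold = if (is.null(sp$exclusion_threshold)) 0.0625
      else sp$exclusion_threshold,
    ld_r2_structure = if (is.null(sp$ld_r2_structure)) 0.2 else
      sp$ld_r2_structure,
    focal_regions = sp$focal_regions)
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stage order: QC (call rate, MAF, optional intragenic exclusion,
#' relaxed LD pruning, relatedness de-duplication) — hybrid index (PCoA
#' projection against pig references and simulated pure genotypes) — ROH
#' detection and F_ROH — exclusion of inbred and hybrid individuals —
#' per-location downsampling — spatial structure (stringently LD-pruned
#' PCoA, population-level Mantel test, axis-geography correlations, MLH
#' and its linear model, optional regional allele clines with kriging).
#' Every intermediate table is written to `output_dir` as TSV/CSV;
#' identical config and inputs produce byte-identical outputs.
#'
#' @param config a YAML path or list accepted by
#'   [load_pipeline_config()].
#' @return invisibly, a list with the headline results (`qc_log`,
#'   `hybrid`, `inbreeding`, `mantel`, `axis_geo`, `mlh_model`,
#'   `report`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- load
  g <- stage("load", {
    g <- read_ped_map(cfg$paths$genotypes_ped, cfg$paths$genotypes_map)
    meta <- read_sample_metadata(cfg$paths$metadata, g)
    attach_metadata(g, meta)
  })
  # pig pool read with the panel's allele orientation so dosages are
  # comparable across files
  pigs <- stage("load", read_ped_map(
    cfg$paths$pigs_ped, cfg$paths$pigs_map,
    ref_alleles = data.frame(locus_id = g$markers$locus_id,
                             allele_b = g$markers$allele_b)))
  pigs$samples$group <- "pig_reference"
  genes <- if (!is.null(cfg$paths$gene_intervals))
    stage("load", read_gene_intervals(cfg$paths$gene_intervals)) else NULL

  # --- qc
  g_qc <- stage("qc", run_qc(g, cfg$qc, genes = genes))
  qc_log <- attr(g_qc, "qc_log")
  write_tsv(qc_log, file.path(out, "qc_log.tsv"))

  # --- hybrid index
  hybrid <- stage("hybrid", {
    pigs_sub <- subset_genotypes(pigs, loci = g_qc$markers$locus_id)
    hybrid_index_stage(g_qc, pigs_sub, n_pure = cfg$hybrid$n_pure,
                       axes_used = cfg$hybrid$axes_used,
                       seed = cfg$seeds$pure)
  })
  wild_scores <- hybrid$scores[hybrid$scores$group == "wild", ]
  write_tsv(wild_scores, file.path(out, "f_hybrid.tsv"))

  # --- ROH / inbreeding
  inb <- stage("roh", {
    scan <- scanned_regions(g_qc$markers, cfg$roh)
    segs <- suppressWarnings(detect_roh(g_qc, cfg$roh))
    fr <- f_roh(segs, g_qc$samples$sample_id, scan$total_bp,
                min_length = cfg$roh$min_length_bp)
    write_tsv(segs, file.path(out, "roh_segments.tsv"))
    write_tsv(fr, file.path(out, "f_roh.tsv"))
    write_tsv(scan$regions, file.path(out, "scanned_regions.tsv"))
    list(f_roh = fr, segments = segs, scanned_bp = scan$total_bp)
  })

  # --- spatial structure
  spatial <- stage("spatial", {
    keep <- exclude_inbred_and_hybrid(wild_scores, inb$f_roh,
                                      cfg$spatial$exclusion_threshold)
    g_str <- subset_genotypes(g_qc, samples = keep)
    keep2 <- downsample_per_location(g_str$samples,
                                     max_n = cfg$spatial$max_per_location,
                                     seed = cfg$seeds$downsample)
    g_str <- subset_genotypes(g_str, samples = keep2)
    cfg2 <- cfg$qc
    cfg2$ld_r2_max <- cfg$spatial$ld_r2_structure
    g_str <- subset_genotypes(g_str, loci = ld_prune(g_str, cfg2))

    dm <- hamming_distance_matrix(g_str)
    ord <- pcoa_ordination(dm, max_axes = 10)
    dm_pop <- location_mean_distance(dm, g_str$samples)
    loc_coord <- stats::aggregate(
      cbind(longitude, latitude) ~ location_id,
      data = as.data.frame(g_str$samples), FUN = mean)
    loc_coord <- loc_coord[match(rownames(dm_pop),
                                 loc_coord$location_id), ]
    d_geo <- geographic_distance_matrix(sample_table(
      loc_coord$location_id, "wild", loc_coord$location_id,
      loc_coord$longitude, loc_coord$latitude))
    mant <- mantel_test(dm_pop, d_geo, n_perm = cfg$spatial$n_perm,
                        seed = cfg$seeds$mantel)
    ageo <- axis_geography_correlation(ord, g_str$samples)
    mlh_tab <- mlh(g_qc)
    mlh_df <- data.frame(
      mlh = mlh_tab$mlh,
      longitude = g_qc$samples$longitude,
      latitude = g_qc$samples$latitude,
      f_hybrid = wild_scores$f_hybrid[
        match(mlh_tab$sample_id, wild_scores$sample_id)],
      f_roh = inb$f_roh$f_roh[
        match(mlh_tab$sample_id, inb$f_roh$sample_id)])
    mlh_fit <- mlh_linear_model(mlh_df)

    write_tsv(mlh_tab, file.path(out, "mlh.tsv"))
    write_tsv(mlh_fit$coefficients, file.path(out, "mlh_model.tsv"))
    write_tsv(data.frame(r = mant$r, p_value = mant$p_value,
                         n_permutations = mant$n_permutations),
              file.path(out, "mantel.tsv"))
    write_tsv(ageo, file.path(out, "axis_geography.tsv"))
    write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates),
              file.path(out, "pcoa_scores.tsv"))

    clines <- list()
    for (focal in cfg$spatial$focal_regions) {
      sel <- select_regional_alleles(g_str, g_str$samples, focal)
      if (nrow(sel) == 0) next
      fr <- mean_regional_frequency(g_str, g_str$samples, sel)
      kr <- krige_allele_frequencies(fr,
                                     grid_step = cfg$spatial$grid_step)
      tag <- paste(focal, collapse = "_")
      utils::write.csv(kr$surface,
                       file.path(out, paste0("cline_", tag, ".csv")),
                       row.names = FALSE, quote = FALSE)
      clines[[tag]] <- kr
    }
    list(mantel = mant, axis_geo = ageo, mlh_model = mlh_fit,
         ordination = ord, clines = clines,
         n_structure_samples = n_samples(g_str))
  })

  report <- data.frame(
    statistic = c("n_samples_qc", "n_loci_qc", "n_structure_samples",
                  "scanned_mb", "mantel_r", "mantel_p",
                  "mlh_model_F", "mlh_model_r2_adj"),
    value = c(n_samples(g_qc), n_loci(g_qc),
              spatial$n_structure_samples,
              round(inb$scanned_bp / 1e6, 3),
              round(spatial$mantel$r, 6),
              spatial$mantel$p_value,
              round(spatial$mlh_model$F_statistic, 4),
              round(spatial$mlh_model$r2_adj, 6)),
    stringsAsFactors = FALSE)
  write_tsv(report, file.path(out, "report.tsv"))

  invisible(list(qc_log = qc_log, hybrid = hybrid,
                 inbreeding = inb, mantel = spatial$mantel,
                 axis_geo = spatial$axis_geo,
                 mlh_model = spatial$mlh_model, report = report))
}
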