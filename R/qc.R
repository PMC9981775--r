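#' Quality-control configuration
#'
#' Bundles the thresholds of the QC chain. Defaults follow the study design
#' this package reimplements: call rates above 0.95 for both loci and
#' samples, minor allele frequency above 0.025, PLINK-style
#' `indep-pairwise` LD pruning with a 50-SNP window and step 5 (relaxed
#' r^2 < 0.5 for ROH work, stringent r^2 < 0.2 for structure analyses),
#' relatedness estimated on loci with MAF > 0.10 and pairs with
#' identity-by-descent score >= 0.183 de-duplicated.
#'
#' @param min_sample_call_rate,min_locus_call_rate call-rate thresholds.
#' @param min_maf minimum minor allele frequency.
#' @param ld_window_snps,ld_step_snps,ld_r2_max LD-pruning window, step and
#'   squared-correlation ceiling.
#' @param relatedness_maf_min MAF floor for loci entering the IBD estimate.
#' @param relatedness_max pairs at or above this pi-hat are considered
#'   related.
#' @param exclude_intragenic whether the pipeline drops intragenic SNPs.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_sample_call_rate = 0.95,
                      min_locus_call_rate = 0.95,
                      min_maf = 0.025,
                      ld_window_snps = 50,
                      ld_step_snps = 5,
                      ld_r2_max = 0.5,
                      relatedness_maf_min = 0.10,
                      relatedness_max = 0.183,
                      exclude_intragenic = TRUE) {
  props <- c(min_sample_call_rate, min_locus_call_rate, min_maf,
             ld_r2_max, relatedness_maf_min, relatedness_max)
  if (any(props < 0 | props > 1))
    stop("qc_config: proportions must lie in [0, 1]")
  if (ld_step_snps < 1 || ld_window_snps <= ld_step_snps)
    stop("qc_config: require ld_window_snps > ld_step_snps >= 1")
  cfg <- list(min_sample_call_rate = min_sample_call_rate,
              min_locus_call_rate = min_locus_call_rate,
              min_maf = min_maf,
              ld_window_snps = as.integer(ld_window_snps),
              ld_step_snps = as.integer(ld_step_snps),
              ld_r2_max = ld_r2_max,
              relatedness_maf_min = relatedness_maf_min,
              relatedness_max = relatedness_max,
              exclude_intragenic = isTRUE(exclude_intragenic))
  class(cfg) <- "qc_config"
  cfg
}

#' Filter loci and samples by call rate
#'
#' Removes first the loci, then the samples, whose genotyping call rate
#' falls below the configured thresholds. The removal log (entity, reason,
#' statistic) is attached as attribute `"removed"`.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return the filtered `genotype_matrix`.
#' @export
filter_call_rate <- function(g, cfg = qc_config()) {
  locus_cr <- colMeans(!is.na(g$dosage))
  keep_l <- locus_cr >= cfg$min_locus_call_rate
  removed <- data.frame(
    entity = colnames(g$dosage)[!keep_l],
    type = rep("locus", sum(!keep_l)),
    reason = rep("call_rate", sum(!keep_l)),
    statistic = unname(locus_cr[!keep_l]),
    stringsAsFactors = FALSE)
  g2 <- subset_genotypes(g, loci = which(keep_l))
  sample_cr <- if (n_loci(g2) > 0) rowMeans(!is.na(g2$dosage)) else
    rep(1, n_samples(g2))
  keep_s <- sample_cr >= cfg$min_sample_call_rate
  removed <- rbind(removed, data.frame(
    entity = rownames(g2$dosage)[!keep_s],
    type = rep("sample", sum(!keep_s)),
    reason = rep("call_rate", sum(!keep_s)),
    statistic = unname(sample_cr[!keep_s]),
    stringsAsFactors = FALSE))
  if (!any(keep_s))
    stop("filter_call_rate: all samples removed at threshold ",
         cfg$min_sample_call_rate)
  out <- subset_genotypes(g2, samples = which(keep_s))
  attr(out, "removed") <- removed
  out
}

#' Per-locus allele frequencies and MAF
#'
#' `allele_b_frequency()` is the frequency of the counted allele
#' (mean dosage / 2 over non-missing genotypes); `minor_allele_frequency()`
#' folds it to `min(p, 1 - p)`. Loci with no non-missing genotype in the
#' subset yield `NA` and are flagged via a warning.
#'
#' @param g a [genotype_matrix()].
#' @param sample_subset optional sample index/id vector.
#' @return numeric vector, one entry per locus, named by locus id.
#' @export
allele_b_frequency <- function(g, sample_subset = NULL) {
  d <- g$dosage
  if (!is.null(sample_subset)) {
    if (is.character(sample_subset))
      sample_subset <- match(sample_subset, g$samples$sample_id)
    d <- d[sample_subset, , drop = FALSE]
    if (nrow(d) == 0) stop("allele frequency: empty sample subset")
  }
  p <- colMeans(d, na.rm = TRUE) / 2
  p[colSums(!is.na(d)) == 0] <- NA_real_
  if (anyNA(p))
    warning(sum(is.na(p)), " loci have no non-missing genotypes; MAF NA")
  p
}

#' @rdname allele_b_frequency
#' @export
minor_allele_frequency <- function(g, sample_subset = NULL) {
  p <- allele_b_frequency(g, sample_subset)
  pmin(p, 1 - p)
}

#' Filter loci by minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()]; loci with MAF <= `min_maf` (or undefined
#'   MAF) are removed.
#' @return the filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, cfg = qc_config()) {
  maf <- suppressWarnings(minor_allele_frequency(g))
  keep <- !is.na(maf) & maf > cfg$min_maf
  subset_genotypes(g, loci = which(keep))
}

#' Windowed LD pruning (indep-pairwise)
#'
#' Greedy sliding-window pruning of loci in strong linkage disequilibrium,
#' after PLINK's `indep-pairwise`: within each window of
#' `ld_window_snps` loci (advancing by `ld_step_snps`), while any retained
#' pair has squared dosage correlation above `ld_r2_max`, the member with
#' the lower MAF (ties: the later map position) is dropped. Windows slide
#' within chromosomes. The result is deterministic given the input order.
#'
#' @param g a [genotype_matrix()] with loci sorted by chromosome and
#'   position (as `marker_map` guarantees).
#' @param cfg a [qc_config()].
#' @return character vector of retained locus ids.
#' @export
ld_prune <- function(g, cfg = qc_config()) {
  if (cfg$ld_window_snps < 2) stop("ld_prune: window must be >= 2 SNPs")
  maf <- suppressWarnings(minor_allele_frequency(g))
  keep <- rep(TRUE, n_loci(g))
  chrom <- g$markers$chromosome
  pos <- g$markers$position_bp
  d <- g$dosage
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nl <- length(idx)
    starts <- seq(1, max(1, nl), by = cfg$ld_step_snps)
    for (s in starts) {
      win <- idx[s:min(s + cfg$ld_window_snps - 1, nl)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r <- suppressWarnings(
          stats::cor(d[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r2 <- r^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= cfg$ld_r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1, ]
        pair <- act[hit]
        # drop the lower-MAF member; tie-break on later position
        drop <- if (isTRUE(maf[pair[1]] < maf[pair[2]])) pair[1]
                else if (isTRUE(maf[pair[2]] < maf[pair[1]])) pair[2]
                else pair[which.max(pos[pair])]
        keep[drop] <- FALSE
      }
    }
  }
  g$markers$locus_id[keep]
}

#' Remove loci inside gene intervals
#'
#' Drops loci whose 1-based position falls inside any interval of a
#' BED-convention (0-based half-open) interval set: a marker at position
#' `p` is intragenic when `start_bp < p <= end_bp`.
#'
#' @param g a [genotype_matrix()].
#' @param genes a [gene_interval_set()].
#' @return character vector of retained (intergenic) locus ids.
#' @export
exclude_intragenic <- function(g, genes) {
  if (nrow(genes) == 0) return(g$markers$locus_id)
  shared <- intersect(unique(g$markers$chromosome),
                      unique(genes$chromosome))
  if (!length(shared))
    stop("exclude_intragenic: no chromosome names shared between markers ",
         "and intervals (naming convention clash?)")
  inside <- rep(FALSE, n_loci(g))
  for (ch in shared) {
    li <- which(g$markers$chromosome == ch)
    iv <- genes[genes$chromosome == ch, , drop = FALSE]
    p <- g$markers$position_bp[li]
    for (k in seq_len(nrow(iv))) {
      inside[li] <- inside[li] | (p > iv$start_bp[k] & p <= iv$end_bp[k])
    }
  }
  g$markers$locus_id[!inside]
}
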