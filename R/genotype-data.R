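#' Construct a marker map
#'
#' A marker map carries the genomic coordinates and allele labels of a
#' biallelic SNP panel. Dosages in a [genotype_matrix()] count copies of
#' `allele_b`; positions are 1-based base pairs. Within each chromosome
#' positions must be strictly increasing once sorted, and locus ids must be
#' unique.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome character (or coercible) chromosome labels.
#' @param position_bp integer base-pair positions (1-based).
#' @param allele_a,allele_b allele labels; `allele_b` is the counted allele.
#'   Defaults are the generic labels "A"/"C" (symbols PED files accept).
#' @return A `data.frame` of class `marker_map`, sorted by chromosome then
#'   position.
#' @export
marker_map <- function(locus_id, chromosome, position_bp,
                       allele_a = rep("A", length(locus_id)),
                       allele_b = rep("C", length(locus_id))) {
  m <- data.frame(
    locus_id = as.character(locus_id),
    chromosome = as.character(chromosome),
    position_bp = as.integer(position_bp),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(m$locus_id))
    stop("marker_map: locus_ids must be unique")
  if (any(m$allele_a == m$allele_b))
    stop("marker_map: allele_a must differ from allele_b at every locus")
  ord <- order(m$chromosome, m$position_bp)
  m <- m[ord, , drop = FALSE]
  rownames(m) <- NULL
  dup_pos <- stats::ave(m$position_bp, m$chromosome,
                        FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(dup_pos > 0))
    stop("marker_map: positions must be strictly increasing within chromosome")
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Construct a sample table
#'
#' Per-sample metadata: group membership (wild, pig reference, simulated pure,
#' or synthetic), sampling location and coordinates, and an optional genetic
#' cluster id used for per-cluster allele-frequency estimation.
#'
#' @param sample_id unique character ids.
#' @param group one of `"wild"`, `"pig_reference"`, `"simulated_pure"`,
#'   `"synthetic"` per sample.
#' @param location_id character location labels (optional, NA allowed).
#' @param longitude,latitude decimal degrees; validated to lie in
#'   \[-180, 180\] and \[-90, 90\] where present.
#' @param cluster_id optional genetic-cluster labels.
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, group,
                         location_id = NA_character_,
                         longitude = NA_real_, latitude = NA_real_,
                         cluster_id = NA_character_) {
  groups <- c("wild", "pig_reference", "simulated_pure", "synthetic")
  n <- length(sample_id)
  s <- data.frame(
    sample_id = as.character(sample_id),
    group = rep_len(as.character(group), n),
    location_id = rep_len(as.character(location_id), n),
    longitude = rep_len(as.numeric(longitude), n),
    latitude = rep_len(as.numeric(latitude), n),
    cluster_id = rep_len(as.character(cluster_id), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(s$sample_id))
    stop("sample_table: sample_ids must be unique")
  bad <- setdiff(unique(s$group), groups)
  if (length(bad))
    stop("sample_table: unknown group(s): ", paste(bad, collapse = ", "))
  if (any(!is.na(s$latitude) & abs(s$latitude) > 90))
    stop("sample_table: latitude outside [-90, 90]")
  if (any(!is.na(s$longitude) & abs(s$longitude) > 180))
    stop("sample_table: longitude outside [-180, 180]")
  rownames(s) <- NULL
  class(s) <- c("sample_table", "data.frame")
  s
}

#' Construct a genotype matrix
#'
#' The central container shared by all pipeline stages: an individuals-by-loci
#' dosage matrix (0/1/2 copies of the counted allele, `NA` = missing) bound to
#' its [marker_map()] and [sample_table()].
#'
#' @param dosage integer matrix, one row per sample, one column per locus.
#' @param markers a [marker_map()] with one row per dosage column.
#' @param samples a [sample_table()] with one row per dosage row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `markers`, `samples`.
#' @export
genotype_matrix <- function(dosage, markers, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples))
    stop("genotype_matrix: dosage rows (", nrow(dosage),
         ") != samples (", nrow(samples), ")")
  if (ncol(dosage) != nrow(markers))
    stop("genotype_matrix: dosage columns (", ncol(dosage),
         ") != markers (", nrow(markers), ")")
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok))
    stop("genotype_matrix: dosage entries must be 0, 1, 2 or NA")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- markers$locus_id
  g <- list(dosage = dosage, markers = markers, samples = samples)
  class(g) <- "genotype_matrix"
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "loci\n")
  cat("  chromosomes:", length(unique(x$markers$chromosome)),
      " missing:", sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  cat("  groups:", paste(names(table(x$samples$group)),
                         table(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param g a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosage)

#' Subset a genotype matrix by samples or loci
#'
#' @param g a [genotype_matrix()].
#' @param samples,loci index vectors (logical, integer, or character ids);
#'   `NULL` keeps everything.
#' @return a new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  li <- if (is.null(loci)) seq_len(n_loci(g)) else loci
  if (is.character(si)) si <- match(si, g$samples$sample_id)
  if (is.character(li)) li <- match(li, g$markers$locus_id)
  if (anyNA(si) || anyNA(li))
    stop("subset_genotypes: unknown sample or locus ids")
  mk <- g$markers[li, , drop = FALSE]
  rownames(mk) <- NULL
  sm <- g$samples[si, , drop = FALSE]
  rownames(sm) <- NULL
  genotype_matrix(g$dosage[si, li, drop = FALSE], mk, sm)
}

#' Flip allele orientation at selected loci
#'
#' Swaps `allele_a`/`allele_b` and maps dosage d to 2 - d (missing stays
#' missing) at the given loci. Recoding is an involution: flipping twice is
#' the identity.
#'
#' @param g a [genotype_matrix()].
#' @param loci indices or ids of loci to flip; default all.
#' @return a `genotype_matrix` with flipped orientation.
#' @export
flip_alleles <- function(g, loci = NULL) {
  li <- if (is.null(loci)) seq_len(n_loci(g)) else loci
  if (is.character(li)) li <- match(li, g$markers$locus_id)
  if (is.logical(li)) li <- which(li)
  d <- g$dosage
  d[, li] <- 2L - d[, li, drop = FALSE]
  m <- g$markers
  tmp <- m$allele_a[li]
  m$allele_a[li] <- m$allele_b[li]
  m$allele_b[li] <- tmp
  genotype_matrix(d, m, g$samples)
}

#' Construct a gene-interval set
#'
#' Genomic intervals (e.g. gene bodies) in BED convention: half-open,
#' 0-based `[start_bp, end_bp)`. Conversion to the package's 1-based marker
#' coordinates happens at point of use ([exclude_intragenic()]).
#'
#' @param chromosome,start_bp,end_bp parallel vectors defining intervals.
#' @return A `data.frame` of class `gene_interval_set`.
#' @export
gene_interval_set <- function(chromosome = character(),
                              start_bp = integer(), end_bp = integer()) {
  iv <- data.frame(
    chromosome = as.character(chromosome),
    start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp),
    stringsAsFactors = FALSE
  )
  if (any(iv$start_bp >= iv$end_bp))
    stop("gene_interval_set: start_bp must be < end_bp")
  class(iv) <- c("gene_interval_set", "data.frame")
  iv
}
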