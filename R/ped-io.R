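#' Read genotypes from PLINK PED/MAP text files
#'
#' Parses the classic whitespace-delimited PLINK text format: the MAP file
#' has one row per locus (chromosome, locus id, genetic position, base-pair
#' position), the PED file one row per sample with six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele columns per locus. "0 0" allele pairs become missing.
#'
#' Dosage counts copies of `allele_b`. PED files do not declare which allele
#' to count, so by default `allele_b` is the lexicographically second
#' observed allele at each locus; a two-column reference table
#' (`locus_id`, `allele_b`) overrides this.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param ref_alleles optional data.frame with columns `locus_id` and
#'   `allele_b` fixing the counted allele.
#' @param permissive if `FALSE` (default), allele symbols outside
#'   `A,C,G,T,1,2,0` raise an error.
#' @return a [genotype_matrix()]; sample metadata carries group `"wild"`
#'   and the PED family id as `location_id`.
#' @export
read_ped_map <- function(ped_path, map_path, ref_alleles = NULL,
                         permissive = FALSE) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("chromosome", "locus_id",
                                         "cm", "position_bp"))
  if (ncol(map) != 4)
    stop("MAP parse error: expected 4 columns, got ", ncol(map))
  nl <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  ns <- length(lines)
  expect_fields <- 6L + 2L * nl
  fam <- iid <- character(ns)
  al1 <- matrix("0", ns, nl)
  al2 <- matrix("0", ns, nl)
  for (i in seq_len(ns)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != expect_fields)
      stop("PED parse error at line ", i, ": expected ", expect_fields,
           " fields, got ", length(f))
    fam[i] <- f[1]
    iid[i] <- f[2]
    gt <- f[-(1:6)]
    al1[i, ] <- gt[seq(1, length(gt), by = 2)]
    al2[i, ] <- gt[seq(2, length(gt), by = 2)]
  }
  if (!permissive) {
    symbols <- unique(c(al1, al2))
    bad <- setdiff(symbols, c("A", "C", "G", "T", "1", "2", "0"))
    if (length(bad))
      stop("PED parse error: unexpected allele symbol(s) ",
           paste(bad, collapse = ", "),
           " (use permissive = TRUE to accept)")
  }

  allele_a <- allele_b <- character(nl)
  dosage <- matrix(NA_integer_, ns, nl)
  ref_b <- NULL
  if (!is.null(ref_alleles)) {
    ref_b <- stats::setNames(as.character(ref_alleles$allele_b),
                             as.character(ref_alleles$locus_id))
  }
  for (j in seq_len(nl)) {
    a1 <- al1[, j]
    a2 <- al2[, j]
    miss <- a1 == "0" | a2 == "0"
    obs <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(obs) > 2)
      stop("locus ", map$locus_id[j], " has >2 alleles: ",
           paste(obs, collapse = ","))
    b <- if (!is.null(ref_b) && !is.na(ref_b[map$locus_id[j]])) {
      ref_b[[map$locus_id[j]]]
    } else if (length(obs) >= 2) {
      obs[2]
    } else {
      NA_character_  # monomorphic or all-missing; placeholder below
    }
    a_lab <- if (length(obs) == 0) "A" else setdiff(obs, b)[1]
    if (is.na(b)) b <- if (length(obs) == 1) "N" else "B"
    if (is.na(a_lab) || !length(a_lab) || a_lab == b)
      a_lab <- if (b == "A") "B" else "A"
    allele_a[j] <- a_lab
    allele_b[j] <- b
    d <- (a1 == b) + (a2 == b)
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }

  mk <- marker_map(map$locus_id, map$chromosome,
                   as.integer(map$position_bp), allele_a, allele_b)
  # marker_map sorts by chromosome/position; reorder dosage to match
  dosage <- dosage[, match(mk$locus_id, map$locus_id), drop = FALSE]
  sm <- sample_table(iid, group = "wild", location_id = fam)
  genotype_matrix(dosage, mk, sm)
}

#' Write genotypes to PLINK PED/MAP text files
#'
#' Inverse of [read_ped_map()]: the written files read back to an identical
#' dosage matrix, marker order and missingness pattern. Missing genotypes
#' are written as "0 0"; the PED family column holds `location_id`
#' (or the sample id when no location is set).
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, `g`.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  m <- g$markers
  utils::write.table(
    data.frame(m$chromosome, m$locus_id, 0, m$position_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  ns <- n_samples(g)
  nl <- n_loci(g)
  fam <- ifelse(is.na(g$samples$location_id), g$samples$sample_id,
                g$samples$location_id)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(ns)) {
    d <- g$dosage[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, m$allele_b, m$allele_a))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, m$allele_b, m$allele_a))
    gt <- character(2L * nl)
    if (nl > 0) {
      gt[seq(1, 2 * nl, by = 2)] <- a1
      gt[seq(2, 2 * nl, by = 2)] <- a2
    }
    writeLines(paste(c(fam[i], g$samples$sample_id[i], "0", "0", "0",
                       "-9", gt), collapse = " "), con)
  }
  invisible(g)
}

#' Read sample metadata from CSV
#'
#' Expects a header with at least `sample_id` and `group`; optional columns
#' `location_id`, `longitude`, `latitude`, `cluster_id`. When a
#' [genotype_matrix()] is supplied, ids are matched against it and
#' mismatches are reported as a warning.
#'
#' @param csv_path path to the CSV file.
#' @param genotypes optional [genotype_matrix()] to match ids against.
#' @return a [sample_table()].
#' @export
read_sample_metadata <- function(csv_path, genotypes = NULL) {
  x <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("sample metadata contains duplicate sample_id values")
  opt <- function(col, default) if (col %in% names(x)) x[[col]] else default
  s <- sample_table(
    sample_id = x$sample_id,
    group = x$group,
    location_id = opt("location_id", NA_character_),
    longitude = opt("longitude", NA_real_),
    latitude = opt("latitude", NA_real_),
    cluster_id = opt("cluster_id", NA_character_)
  )
  if (!is.null(genotypes)) {
    unmatched <- setdiff(s$sample_id, genotypes$samples$sample_id)
    if (length(unmatched))
      warning("metadata ids not present in genotypes: ",
              paste(unmatched, collapse = ", "))
  }
  s
}

#' Read gene intervals from a BED file
#'
#' BED3+: chromosome, start, end (half-open, 0-based). Extra columns are
#' ignored. Overlapping intervals are retained as-is; membership tests use
#' their union.
#'
#' @param bed_path path to the BED file.
#' @return a [gene_interval_set()].
#' @export
read_gene_intervals <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  info <- file.info(bed_path)
  if (info$size == 0) return(gene_interval_set())
  x <- utils::read.table(bed_path, header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3)
    stop("BED parse error: expected >= 3 columns, got ", ncol(x))
  gene_interval_set(x[[1]], x[[2]], x[[3]])
}

#' Attach metadata to a genotype matrix
#'
#' Replaces the sample table of `g` with rows of `meta` matched by id;
#' samples without metadata keep their existing row.
#'
#' @param g a [genotype_matrix()].
#' @param meta a [sample_table()].
#' @return a `genotype_matrix` with updated sample table.
#' @export
attach_metadata <- function(g, meta) {
  s <- g$samples
  idx <- match(s$sample_id, meta$sample_id)
  hit <- !is.na(idx)
  for (col in c("group", "location_id", "longitude", "latitude",
                "cluster_id")) {
    s[[col]][hit] <- meta[[col]][idx[hit]]
  }
  genotype_matrix(g$dosage, g$markers, s)
}
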