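#' Genetic map of a pig-like genome
#'
#' Chromosome names, physical lengths and genetic lengths. The default is
#' an 18-autosome genome of roughly 2.26 Gb (approximate Sus scrofa
#' autosome sizes) at 1 cM/Mb, i.e. about 22.6 Morgans in total.
#'
#' @param chromosomes optional data.frame with columns `name`,
#'   `length_bp`, `length_morgans`.
#' @param n_chromosomes use only the first n default autosomes.
#' @return a data.frame of class `genetic_map`.
#' @export
genetic_map <- function(chromosomes = NULL, n_chromosomes = 18) {
  if (is.null(chromosomes)) {
    mb <- c(274, 151, 133, 131, 105, 171, 121, 139, 139, 69, 79, 61,
            208, 142, 141, 80, 63, 56)[seq_len(n_chromosomes)]
    chromosomes <- data.frame(
      name = as.character(seq_along(mb)),
      length_bp = mb * 1e6,
      length_morgans = mb / 100,
      stringsAsFactors = FALSE)
  }
  if (any(chromosomes$length_bp <= 0 | chromosomes$length_morgans <= 0))
    stop("genetic_map: lengths must be positive")
  class(chromosomes) <- c("genetic_map", "data.frame")
  chromosomes
}

#' Regularly spaced marker map over a genetic map
#'
#' One marker every `spacing_bp` (default 100 kb, at which the ROH
#' criteria of 50 SNPs / 5 Mb / 1 per 150 kb are satisfiable), positions
#' at spacing/2, 3 spacing/2, ...
#'
#' @param gmap a [genetic_map()].
#' @param spacing_bp inter-marker spacing in bp.
#' @return a [marker_map()].
#' @export
make_marker_map <- function(gmap, spacing_bp = 1e5) {
  pos <- list()
  chrom <- list()
  for (i in seq_len(nrow(gmap))) {
    p <- seq(spacing_bp / 2, gmap$length_bp[i], by = spacing_bp)
    pos[[i]] <- p
    chrom[[i]] <- rep(gmap$name[i], length(p))
  }
  pos <- unlist(pos)
  chrom <- unlist(chrom)
  marker_map(sprintf("snp_%s_%d", chrom, unlist(lapply(
    split(seq_along(chrom), factor(chrom, unique(chrom))), seq_along))),
    chrom, pos)
}

new_pedigree <- function(id, sire, dam, population, proband) {
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    population = population, stringsAsFactors = FALSE)
  # parents must precede offspring
  for (i in seq_len(nrow(ped))) {
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(par) && !(par %in% ped$id[seq_len(i - 1)]))
        stop("pedigree: parent ", par, " not defined before ", ped$id[i])
    }
  }
  attr(ped, "proband") <- proband
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Pedigree builders
#'
#' Predefined pedigrees consumed by [gene_drop()]. Founders carry a
#' population label (`"wild"` or `"pig"`); the individual whose genome is
#' of interest is flagged in attribute `"proband"`.
#'
#' `pedigree_backcross(depth)`: a pig founder crossed into wild, then
#' backcrossed to new wild founders; the depth-g proband has expected pig
#' ancestry 2^-g (depth 1 = F1: 0.5; depth 2: 0.25; ...).
#'
#' `pedigree_half_sib()`, `pedigree_full_cousin()`,
#' `pedigree_half_cousin()`: matings between half siblings, full first
#' cousins and half first cousins; the proband's expected autozygosity is
#' 1/8, 1/16 and 1/32 respectively.
#'
#' @param depth backcross generation depth (>= 1).
#' @return a `pedigree` data.frame.
#' @export
pedigree_backcross <- function(depth = 2) {
  if (depth < 1) stop("pedigree_backcross: depth must be >= 1")
  id <- c("pig0", paste0("wild", seq_len(depth)),
          paste0("hyb", seq_len(depth)))
  sire <- c(rep(NA, depth + 1), "pig0",
            if (depth > 1) paste0("hyb", seq_len(depth - 1)))
  dam <- c(rep(NA, depth + 1), paste0("wild", seq_len(depth)))
  pop <- c("pig", rep("wild", depth), rep(NA, depth))
  new_pedigree(id, sire, dam, pop, proband = paste0("hyb", depth))
}

#' @rdname pedigree_backcross
#' @export
pedigree_half_sib <- function() {
  new_pedigree(
    id = c("A", "B", "C", "S1", "S2", "X"),
    sire = c(NA, NA, NA, "A", "A", "S1"),
    dam = c(NA, NA, NA, "B", "C", "S2"),
    population = c("wild", "wild", "wild", NA, NA, NA),
    proband = "X")
}

#' @rdname pedigree_backcross
#' @export
pedigree_full_cousin <- function() {
  new_pedigree(
    id = c("A", "B", "C", "D", "S1", "S2", "P1", "P2", "X"),
    sire = c(NA, NA, NA, NA, "A", "A", "S1", "S2", "P1"),
    dam = c(NA, NA, NA, NA, "B", "B", "C", "D", "P2"),
    population = c(rep("wild", 4), rep(NA, 5)),
    proband = "X")
}

#' @rdname pedigree_backcross
#' @export
pedigree_half_cousin <- function() {
  new_pedigree(
    id = c("A", "B", "C", "D", "E", "S1", "S2", "P1", "P2", "X"),
    sire = c(NA, NA, NA, NA, NA, "A", "A", "S1", "S2", "P1"),
    dam = c(NA, NA, NA, NA, NA, "B", "C", "D", "E", "P2"),
    population = c(rep("wild", 5), rep(NA, 5)),
    proband = "X")
}

#' @rdname pedigree_backcross
#' @export
pedigree_full_sib <- function() {
  new_pedigree(
    id = c("A", "B", "S1", "S2", "X"),
    sire = c(NA, NA, "A", "A", "S1"),
    dam = c(NA, NA, "B", "B", "S2"),
    population = c("wild", "wild", NA, NA, NA),
    proband = "X")
}

# one meiosis: recombine a parent's two haplotypes on one chromosome.
# haplotypes are run-length lists: end positions (bp, increasing,
# last = chromosome length) and founder-haplotype ids.
recombine_haplotypes <- function(hA, hB, morgans, length_bp) {
  nxo <- stats::rpois(1, morgans)
  xo <- sort(stats::runif(nxo, 0, length_bp))
  start_a <- stats::runif(1) < 0.5
  bp <- sort(unique(c(hA$end, hB$end, xo)))
  mid <- (c(0, bp[-length(bp)]) + bp) / 2
  on_a <- (findInterval(mid, xo) %% 2 == 0) == start_a
  idA <- hA$id[findInterval(mid, hA$end, left.open = TRUE) + 1L]
  idB <- hB$id[findInterval(mid, hB$end, left.open = TRUE) + 1L]
  id <- ifelse(on_a, idA, idB)
  keep <- c(id[-1] != id[-length(id)], TRUE)
  list(end = bp[keep], id = id[keep])
}

hap_id_at <- function(h, pos) {
  h$id[findInterval(pos, h$end, left.open = TRUE) + 1L]
}

#' Gene-drop simulation down a pedigree
#'
#' Simulates transmission of founder haplotypes with recombination
#' (Haldane model: crossover count Poisson(chromosome Morgans), positions
#' uniform, no interference) and reports, for each replicate proband (or
#' all individuals): genotypes at the marker positions, the true fraction
#' of the genome descending from pig founders, the true autozygous (IBD)
#' fraction, and the IBD tract list. Founder haplotype alleles are drawn
#' per locus from the founder population's frequency vector.
#'
#' @param ped a pedigree (see [pedigree_backcross()] and friends).
#' @param gmap a [genetic_map()].
#' @param founder_freqs named list: population label -> counted-allele
#'   frequency vector over the markers.
#' @param markers a [marker_map()] over the chromosomes of `gmap`
#'   (default [make_marker_map()]).
#' @param n_rep number of independent replicates of the pedigree.
#' @param seed RNG seed.
#' @param keep `"proband"` (default) or `"all"` individuals.
#' @return list: `genotypes` (a [genotype_matrix()], group
#'   `"synthetic"`), `truth` (sample_id, pedigree_id, pig_ancestry,
#'   ibd_fraction), `ibd_tracts` (sample_id, chromosome, start_bp,
#'   end_bp).
#' @export
gene_drop <- function(ped, gmap, founder_freqs, markers = NULL,
                      n_rep = 1, seed = 1L, keep = c("proband", "all")) {
  keep <- match.arg(keep)
  if (is.null(markers)) markers <- make_marker_map(gmap)
  set.seed(seed)
  nl <- nrow(markers)
  total_bp <- sum(gmap$length_bp)
  founders <- which(is.na(ped$sire) & is.na(ped$dam))
  if (!all(ped$population[founders] %in% names(founder_freqs)))
    stop("gene_drop: founder population without frequency vector")
  keep_ids <- if (keep == "proband") attr(ped, "proband") else ped$id
  chrom_idx <- lapply(gmap$name,
                      function(ch) which(markers$chromosome == ch))

  geno <- list(); truth <- list(); tracts <- list()
  out_i <- 0L
  for (r in seq_len(n_rep)) {
    # founder haplotype alleles
    n_f <- length(founders)
    hap_alleles <- matrix(0L, 2 * n_f, nl)
    for (fi in seq_len(n_f)) {
      fr <- founder_freqs[[ped$population[founders[fi]]]]
      hap_alleles[2 * fi - 1, ] <- stats::rbinom(nl, 1, fr)
      hap_alleles[2 * fi, ] <- stats::rbinom(nl, 1, fr)
    }
    hap_pop <- rep(ped$population[founders], each = 2)

    # drop haplotypes down the pedigree
    haps <- vector("list", nrow(ped))  # [[ind]][[1|2]][[chrom]]
    names(haps) <- ped$id
    for (i in seq_len(nrow(ped))) {
      if (i %in% founders) {
        fi <- match(i, founders)
        haps[[i]] <- lapply(c(2 * fi - 1, 2 * fi), function(hid) {
          lapply(gmap$length_bp, function(L) list(end = L, id = hid))
        })
      } else {
        par <- lapply(c(ped$sire[i], ped$dam[i]),
                      function(p) haps[[match(p, ped$id)]])
        haps[[i]] <- lapply(par, function(ph) {
          lapply(seq_len(nrow(gmap)), function(ci) {
            recombine_haplotypes(ph[[1]][[ci]], ph[[2]][[ci]],
                                 gmap$length_morgans[ci],
                                 gmap$length_bp[ci])
          })
        })
      }
    }

    for (id in keep_ids) {
      ii <- match(id, ped$id)
      h <- haps[[ii]]
      out_i <- out_i + 1L
      sample_id <- sprintf("rep%04d_%s", r, id)
      d <- integer(nl)
      pig_len <- 0
      ibd_len <- 0
      tr <- list(); tk <- 0L
      for (ci in seq_len(nrow(gmap))) {
        h1 <- h[[1]][[ci]]; h2 <- h[[2]][[ci]]
        mi <- chrom_idx[[ci]]
        if (length(mi)) {
          id1 <- hap_id_at(h1, markers$position_bp[mi])
          id2 <- hap_id_at(h2, markers$position_bp[mi])
          d[mi] <- hap_alleles[cbind(id1, mi)] +
            hap_alleles[cbind(id2, mi)]
        }
        for (hh in list(h1, h2)) {
          seg_len <- diff(c(0, hh$end))
          pig_len <- pig_len + sum(seg_len[hap_pop[hh$id] == "pig"])
        }
        bp <- sort(unique(c(h1$end, h2$end)))
        mid <- (c(0, bp[-length(bp)]) + bp) / 2
        same <- hap_id_at(h1, mid) == hap_id_at(h2, mid)
        if (any(same)) {
          seg_start <- c(0, bp[-length(bp)])
          rl <- rle(same)
          e <- cumsum(rl$lengths); s <- e - rl$lengths + 1L
          for (t in which(rl$values)) {
            tk <- tk + 1L
            tr[[tk]] <- data.frame(
              sample_id = sample_id, chromosome = gmap$name[ci],
              start_bp = seg_start[s[t]] + 1, end_bp = bp[e[t]],
              stringsAsFactors = FALSE)
            ibd_len <- ibd_len + bp[e[t]] - seg_start[s[t]]
          }
        }
      }
      geno[[out_i]] <- d
      truth[[out_i]] <- data.frame(
        sample_id = sample_id, pedigree_id = id,
        pig_ancestry = pig_len / (2 * total_bp),
        ibd_fraction = ibd_len / total_bp,
        stringsAsFactors = FALSE)
      if (tk) tracts[[length(tracts) + 1L]] <- do.call(rbind, tr)
    }
  }
  truth <- do.call(rbind, truth)
  dosage <- do.call(rbind, geno)
  sm <- sample_table(truth$sample_id, group = "synthetic")
  list(
    genotypes = genotype_matrix(dosage, markers, sm),
    truth = truth,
    ibd_tracts = if (length(tracts)) do.call(rbind, tracts) else
      data.frame(sample_id = character(), chromosome = character(),
                 start_bp = numeric(), end_bp = numeric(),
                 stringsAsFactors = FALSE)
  )
}
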