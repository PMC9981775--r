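# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Pedigree inbreeding coefficient of the proband by the tabular
# (recursive kinship) method: F = kinship(sire, dam).
pedigree_inbreeding_oracle <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- match(ped$sire[i], ped$id)
    di <- match(ped$dam[i], ped$id)
    for (j in seq_len(i)) {
      if (i == j) {
        fi <- if (!is.na(si) && !is.na(di)) phi[si, di] else 0
        phi[i, i] <- 0.5 * (1 + fi)
      } else {
        v <- 0
        if (!is.na(si)) v <- v + 0.5 * phi[si, j]
        if (!is.na(di)) v <- v + 0.5 * phi[di, j]
        phi[i, j] <- phi[j, i] <- v
      }
    }
  }
  pr <- match(attr(ped, "proband"), ped$id)
  phi[match(ped$sire[pr], ped$id), match(ped$dam[pr], ped$id)]
}

# Exhaustive ROH scanner for one sample on one chromosome, in the regime
# window_max_missing = 0, hit threshold < 1/window_snps: enumerate maximal
# homozygous (non-missing, non-het) runs, keep runs of at least
# window_snps SNPs, split at gaps, apply the segment filters.
roh_oracle_one <- function(d, pos, cfg) {
  hom <- !is.na(d) & d != 1L
  r <- rle(hom)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  segs <- list()
  for (t in which(r$values)) {
    idx <- s[t]:e[t]
    if (length(idx) < cfg$window_snps) next
    gp <- which(diff(pos[idx]) > cfg$max_gap_bp)
    ss <- c(1L, gp + 1L)
    ee <- c(gp, length(idx))
    for (u in seq_along(ss)) {
      ii <- idx[ss[u]:ee[u]]
      nn <- length(ii)
      len <- pos[ii[nn]] - pos[ii[1]] + 1
      if (nn >= cfg$min_snps && len >= cfg$min_length_bp &&
          len / nn <= cfg$min_density_bp_per_snp) {
        segs[[length(segs) + 1L]] <-
          data.frame(start_bp = pos[ii[1]], end_bp = pos[ii[nn]],
                     n_snps = nn, length_bp = len)
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else
    data.frame(start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), length_bp = numeric())
}

# Brute-force scanned-regions total: union over all marker index pairs
# (i, j) satisfying the gap, count, length and density criteria.
scanned_oracle_one <- function(pos, cfg) {
  n <- length(pos)
  iv <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < cfg$min_snps) next
      if (any(diff(pos[i:j]) > cfg$max_gap_bp)) next
      len <- pos[j] - pos[i] + 1
      if (len < cfg$min_length_bp) next
      if (len / (j - i + 1) > cfg$min_density_bp_per_snp) next
      iv[[length(iv) + 1L]] <- c(pos[i], pos[j])
    }
  }
  if (!length(iv)) return(0)
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; lo <- m[1, 1]; hi <- m[1, 2]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, 1] <= hi + 1) {
      hi <- max(hi, m[r, 2])
    } else {
      tot <- tot + hi - lo + 1
      lo <- m[r, 1]; hi <- m[r, 2]
    }
  }
  tot + hi - lo + 1
}

# Weir-Cockerham FST over two populations from dosage matrices.
wc_fst_oracle <- function(d1, d2) {
  r <- 2
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  h1 <- colMeans(d1 == 1, na.rm = TRUE)
  h2 <- colMeans(d2 == 1, na.rm = TRUE)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# All permutations of 1..n (independent of the package's enumerator).
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(sub, n)
    block <- t(apply(block, 1, function(p) append(p[-n], n, after = i - 1)))
    out <- rbind(out, block)
  }
  out
}

# Small genotype matrix from an explicit dosage matrix.
toy_genotypes <- function(d, chrom = NULL, pos = NULL, group = "wild",
                          location = NA_character_) {
  d <- as.matrix(d)
  nl <- ncol(d)
  if (is.null(chrom)) chrom <- rep("1", nl)
  if (is.null(pos)) pos <- seq_len(nl) * 1000
  mk <- boargen::marker_map(paste0("L", seq_len(nl)), chrom, pos)
  sm <- boargen::sample_table(paste0("S", seq_len(nrow(d))), group,
                              location_id = location)
  boargen::genotype_matrix(d, mk, sm)
}
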