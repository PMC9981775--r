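#' Runs-of-homozygosity configuration
#'
#' Parameters of the PLINK-homozyg-style sliding-window detector. Study
#' defaults: 70-SNP windows with no heterozygotes allowed, segments of at
#' least 5 Mb and 50 SNPs with a mean density of at least 1 SNP per
#' 150 kb and a maximum inter-SNP gap of 500 kb. The per-window missing
#' allowance (5) and the per-SNP hit-proportion threshold (0.05) follow
#' the detector's conventional defaults and are exposed here.
#'
#' @param window_snps window length in SNPs.
#' @param window_max_het maximum heterozygotes per homozygous window.
#' @param window_max_missing maximum missing calls per homozygous window.
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   covering a SNP for it to enter a candidate run.
#' @param min_length_bp minimum segment length (default 5 Mb).
#' @param min_snps minimum SNPs per segment.
#' @param min_density_bp_per_snp maximum mean bp per SNP in a segment.
#' @param max_gap_bp maximum inter-SNP distance within a segment.
#' @return a list of class `roh_config`.
#' @export
roh_config <- function(window_snps = 70,
                       window_max_het = 0,
                       window_max_missing = 5,
                       window_hit_threshold = 0.05,
                       min_length_bp = 5e6,
                       min_snps = 50,
                       min_density_bp_per_snp = 150e3,
                       max_gap_bp = 500e3) {
  if (min_length_bp <= 0) stop("roh_config: min_length_bp must be > 0")
  if (any(c(window_snps, window_max_het, window_max_missing,
            min_snps) < 0))
    stop("roh_config: counts must be >= 0")
  cfg <- list(window_snps = as.integer(window_snps),
              window_max_het = as.integer(window_max_het),
              window_max_missing = as.integer(window_max_missing),
              window_hit_threshold = window_hit_threshold,
              min_length_bp = min_length_bp,
              min_snps = as.integer(min_snps),
              min_density_bp_per_snp = min_density_bp_per_snp,
              max_gap_bp = max_gap_bp)
  class(cfg) <- "roh_config"
  cfg
}

#' Genome regions where ROH are detectable
#'
#' The denominator of F_ROH: maximal chromosome stretches over which a
#' segment passing the configured criteria could in principle be called.
#' Markers are split at gaps exceeding `max_gap_bp`; within each stretch,
#' the union of marker spans `[pos_i, pos_j]` satisfying the SNP-count,
#' length and density criteria is reported.
#'
#' @param m a [marker_map()].
#' @param cfg a [roh_config()].
#' @return list: `regions` (a [gene_interval_set()]-like data.frame with
#'   1-based inclusive coordinates) and `total_bp`.
#' @export
scanned_regions <- function(m, cfg = roh_config()) {
  regions <- list()
  k <- 0L
  for (ch in unique(m$chromosome)) {
    pos <- m$position_bp[m$chromosome == ch]
    splits <- which(diff(pos) > cfg$max_gap_bp)
    starts <- c(1L, splits + 1L)
    ends <- c(splits, length(pos))
    for (s in seq_along(starts)) {
      p <- pos[starts[s]:ends[s]]
      n <- length(p)
      if (n < cfg$min_snps) next
      # union over i of [p_i, p_jmax(i)] with (i, j) satisfying criteria
      lo <- hi <- numeric(0)
      for (i in seq_len(n - cfg$min_snps + 1)) {
        js <- seq(i + cfg$min_snps - 1, n)
        span <- p[js] - p[i] + 1
        ok <- span >= cfg$min_length_bp &
          span <= cfg$min_density_bp_per_snp * (js - i + 1)
        if (any(ok)) {
          lo <- c(lo, p[i])
          hi <- c(hi, p[max(js[ok])])
        }
      }
      if (!length(lo)) next
      # merge overlapping spans
      o <- order(lo)
      lo <- lo[o]; hi <- hi[o]
      cur_lo <- lo[1]; cur_hi <- hi[1]
      for (t in seq_along(lo)[-1]) {
        if (lo[t] <= cur_hi + 1) {
          cur_hi <- max(cur_hi, hi[t])
        } else {
          k <- k + 1L
          regions[[k]] <- data.frame(chromosome = ch, start_bp = cur_lo,
                                     end_bp = cur_hi)
          cur_lo <- lo[t]; cur_hi <- hi[t]
        }
      }
      k <- k + 1L
      regions[[k]] <- data.frame(chromosome = ch, start_bp = cur_lo,
                                 end_bp = cur_hi)
    }
  }
  if (!k) {
    reg <- data.frame(chromosome = character(), start_bp = numeric(),
                      end_bp = numeric(), stringsAsFactors = FALSE)
  } else {
    reg <- do.call(rbind, regions)
  }
  list(regions = reg, total_bp = sum(reg$end_bp - reg$start_bp + 1))
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan per sample and chromosome: a window of
#' `window_snps` consecutive SNPs is homozygous when it contains at most
#' `window_max_het` heterozygotes and `window_max_missing` missing calls.
#' Each SNP's hit proportion is the fraction of windows covering it that
#' are homozygous; SNPs at or above `window_hit_threshold` form candidate
#' runs. Candidate runs are split at inter-SNP gaps above `max_gap_bp`,
#' trimmed so both ends are homozygous non-missing calls, and filtered by
#' the segment criteria (`min_snps`, `min_length_bp`, mean density).
#' Segment boundaries are the outermost homozygous SNP positions.
#'
#' @param g a [genotype_matrix()] (markers sorted, as guaranteed).
#' @param cfg a [roh_config()].
#' @return data.frame: `sample_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, cfg = roh_config()) {
  out <- list()
  k <- 0L
  chroms <- unique(g$markers$chromosome)
  for (ch in chroms) {
    li <- which(g$markers$chromosome == ch)
    if (length(li) < cfg$window_snps) {
      warning("detect_roh: chromosome ", ch, " has fewer than ",
              cfg$window_snps, " markers; skipped")
      next
    }
    pos <- g$markers$position_bp[li]
    nl <- length(li)
    w <- cfg$window_snps
    nw <- nl - w + 1L
    for (si in seq_len(n_samples(g))) {
      d <- g$dosage[si, li]
      het <- as.integer(!is.na(d) & d == 1L)
      mis <- as.integer(is.na(d))
      cs_h <- c(0L, cumsum(het))
      cs_m <- c(0L, cumsum(mis))
      wh <- cs_h[(w + 1):(nl + 1)] - cs_h[1:nw]
      wm <- cs_m[(w + 1):(nl + 1)] - cs_m[1:nw]
      hom_win <- as.integer(wh <= cfg$window_max_het &
                              wm <= cfg$window_max_missing)
      # per-SNP: windows covering SNP j start in [j-w+1, j] ∩ [1, nw]
      cs_w <- c(0L, cumsum(hom_win))
      j <- seq_len(nl)
      first <- pmax(j - w + 1L, 1L)
      last <- pmin(j, nw)
      covered <- last - first + 1L
      hits <- cs_w[last + 1L] - cs_w[first]
      prop <- ifelse(covered > 0, hits / covered, 0)
      cand <- prop >= cfg$window_hit_threshold
      segs <- candidate_runs(cand, pos, d, cfg)
      if (nrow(segs)) {
        k <- k + 1L
        segs$sample_id <- g$samples$sample_id[si]
        segs$chromosome <- ch
        out[[k]] <- segs
      }
    }
  }
  if (!k) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample_id", "chromosome", "start_bp", "end_bp", "n_snps",
          "length_bp")]
}

# split candidate runs at large gaps, trim to homozygous ends, filter
candidate_runs <- function(cand, pos, d, cfg) {
  segs <- data.frame(start_bp = numeric(), end_bp = numeric(),
                     n_snps = integer(), length_bp = numeric(),
                     stringsAsFactors = FALSE)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (t in which(r$values)) {
    idx <- starts[t]:ends[t]
    # split at gaps
    gp <- which(diff(pos[idx]) > cfg$max_gap_bp)
    sub_s <- c(1L, gp + 1L)
    sub_e <- c(gp, length(idx))
    for (u in seq_along(sub_s)) {
      ii <- idx[sub_s[u]:sub_e[u]]
      hom <- !is.na(d[ii]) & d[ii] != 1L
      if (!any(hom)) next
      ii <- ii[min(which(hom)):max(which(hom))]
      n <- length(ii)
      len <- pos[ii[n]] - pos[ii[1]] + 1
      if (n < cfg$min_snps) next
      if (len < cfg$min_length_bp) next
      if (len / n > cfg$min_density_bp_per_snp) next
      segs <- rbind(segs, data.frame(
        start_bp = pos[ii[1]], end_bp = pos[ii[n]], n_snps = n,
        length_bp = len, stringsAsFactors = FALSE))
    }
  }
  segs
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH = total length of called segments at or above `min_length` /
#' total scanned-genome length. Individuals are classified against
#' pedigree expectations: 0.125, 0.0625 and 0.03125 are the expected
#' autozygosity of offspring of half siblings, full cousins and half
#' cousins.
#'
#' @param segs output of [detect_roh()].
#' @param sample_ids ids to report (so segment-free samples get 0).
#' @param scanned_total_bp denominator from [scanned_regions()].
#' @param min_length segments below this length are ignored (default
#'   5 Mb).
#' @return data.frame: `sample_id`, `f_roh`, `scanned_bp`,
#'   `inbred_class`.
#' @export
f_roh <- function(segs, sample_ids, scanned_total_bp,
                  min_length = 5e6) {
  if (scanned_total_bp <= 0)
    stop("f_roh: scanned genome length must be positive")
  use <- segs[segs$length_bp >= min_length, , drop = FALSE]
  tot <- tapply(use$length_bp, use$sample_id, sum)
  f <- as.numeric(tot[sample_ids]) / scanned_total_bp
  f[is.na(f)] <- 0
  cls <- rep("below", length(f))
  cls[f >= 0.03125 & f < 0.0625] <- "half_cousins"
  cls[f >= 0.0625 & f < 0.125] <- "full_cousins"
  cls[f >= 0.125] <- "half_siblings_or_more"
  data.frame(sample_id = sample_ids, f_roh = f,
             scanned_bp = scanned_total_bp, inbred_class = cls,
             stringsAsFactors = FALSE)
}
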