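#' Method-of-moments identity-by-descent relatedness
#'
#' Estimates, for sample pairs, the probabilities of sharing 0, 1 or 2
#' alleles identical by descent from identity-by-state counts given sample
#' allele frequencies — the classic PLINK `--genome` moment estimator —
#' and summarises each pair as pi-hat = P(IBD=2) + P(IBD=1)/2. Negative
#' component estimates are truncated to zero and the triple renormalised;
#' pi-hat is clamped to \[0, 1\].
#'
#' Loci are restricted to MAF > `relatedness_maf_min` (estimates at rare
#' loci are uninformative). By default the estimator runs separately per
#' sampling location — allele frequencies, the MAF filter and the pairs
#' all come from that location's samples — which keeps shared
#' population-level drift from masquerading as relatedness.
#' `within_location = FALSE` runs one global pass over all pairs.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @param within_location run per `location_id` (default `TRUE`).
#' @return data.frame with columns `sample_1`, `sample_2`, `ibd_score`.
#' @export
estimate_ibd <- function(g, cfg = qc_config(), within_location = TRUE) {
  ids <- g$samples$sample_id
  loc <- g$samples$location_id
  groups <- if (within_location) {
    split(seq_along(ids), loc)
  } else {
    list(all = seq_along(ids))
  }
  out <- list()
  for (grp in groups) {
    if (length(grp) < 2) next
    maf <- suppressWarnings(minor_allele_frequency(g, sample_subset = grp))
    use <- which(!is.na(maf) & maf > cfg$relatedness_maf_min)
    if (length(use) < 100)
      warning("estimate_ibd: only ", length(use),
              " informative loci; estimates unstable")
    d <- g$dosage[grp, use, drop = FALSE]
    p <- unname(allele_b_frequency(g, sample_subset = grp)[use])
    q <- 1 - p

    # expected IBS-state mass given IBD state, summed over loci
    e0_ibs0 <- sum(2 * p^2 * q^2)
    e0_ibs1 <- sum(4 * p^3 * q + 4 * p * q^3)
    e0_ibs2 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
    e1_ibs1 <- sum(2 * p^2 * q + 2 * p * q^2)
    e1_ibs2 <- sum(p^3 + q^3 + p^2 * q + p * q^2)

    for (a in seq_len(length(grp) - 1)) {
      for (b in seq(a + 1, length(grp))) {
        gi <- d[a, ]
        gj <- d[b, ]
        ok <- !is.na(gi) & !is.na(gj)
        nm <- sum(ok)
        score <- NA_real_
        if (nm > 0) {
          ibs <- 2 - abs(gi[ok] - gj[ok])
          n0 <- sum(ibs == 0)
          n1 <- sum(ibs == 1)
          n2 <- sum(ibs == 2)
          sc <- nm / length(p)  # rescale expectations to typed loci
          p0 <- n0 / (e0_ibs0 * sc)
          p1 <- (n1 - p0 * e0_ibs1 * sc) / (e1_ibs1 * sc)
          p2 <- (n2 - p0 * e0_ibs2 * sc - p1 * e1_ibs2 * sc) / nm
          pr <- pmax(c(p0, p1, p2), 0)
          pr <- pr / sum(pr)
          score <- min(max(pr[3] + pr[2] / 2, 0), 1)
        }
        out[[length(out) + 1L]] <- data.frame(
          sample_1 = ids[grp[a]], sample_2 = ids[grp[b]],
          ibd_score = score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_1 = character(), sample_2 = character(),
                      ibd_score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove related individuals
#'
#' Iteratively removes the individual participating in the most pairs with
#' `ibd_score >= relatedness_max` until no such pair remains. Ties are
#' broken deterministically: the member with the lower call rate goes
#' first, then the later sample in id order.
#'
#' @param g a [genotype_matrix()].
#' @param scores output of [estimate_ibd()].
#' @param cfg a [qc_config()].
#' @return the de-duplicated `genotype_matrix`; removed ids in attribute
#'   `"removed"`.
#' @export
drop_related <- function(g, scores, cfg = qc_config()) {
  rel <- scores[!is.na(scores$ibd_score) &
                  scores$ibd_score >= cfg$relatedness_max, , drop = FALSE]
  call_rate <- rowMeans(!is.na(g$dosage))
  names(call_rate) <- g$samples$sample_id
  removed <- character()
  while (nrow(rel) > 0) {
    cnt <- table(c(rel$sample_1, rel$sample_2))
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1) {
      cr <- call_rate[cand]
      cand <- cand[cr == min(cr)]
      cand <- sort(cand, decreasing = TRUE)[1]
    }
    victim <- cand[1]
    removed <- c(removed, victim)
    rel <- rel[rel$sample_1 != victim & rel$sample_2 != victim, ,
               drop = FALSE]
  }
  out <- subset_genotypes(
    g, samples = which(!g$samples$sample_id %in% removed))
  attr(out, "removed") <- removed
  out
}

#' Run the full QC chain
#'
#' Fixed stage order: locus call rate, sample call rate, MAF, intragenic
#' exclusion (optional), LD pruning, relatedness de-duplication. Returns
#' the filtered matrix; a per-stage count log is attached as attribute
#' `"qc_log"`.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @param genes optional [gene_interval_set()] for intragenic exclusion.
#' @return the QC'd `genotype_matrix`.
#' @export
run_qc <- function(g, cfg = qc_config(), genes = NULL) {
  log <- list(input = c(n_samples(g), n_loci(g)))
  g <- filter_call_rate(g, cfg)
  log$call_rate <- c(n_samples(g), n_loci(g))
  g <- filter_maf(g, cfg)
  log$maf <- c(n_samples(g), n_loci(g))
  if (cfg$exclude_intragenic && !is.null(genes) && nrow(genes) > 0) {
    g <- subset_genotypes(g, loci = exclude_intragenic(g, genes))
    log$intragenic <- c(n_samples(g), n_loci(g))
  }
  g <- subset_genotypes(g, loci = ld_prune(g, cfg))
  log$ld_prune <- c(n_samples(g), n_loci(g))
  scores <- suppressWarnings(estimate_ibd(g, cfg))
  g <- drop_related(g, scores, cfg)
  log$relatedness <- c(n_samples(g), n_loci(g))
  qc_log <- data.frame(
    stage = names(log),
    n_samples = vapply(log, `[`, numeric(1), 1),
    n_loci = vapply(log, `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )
  rownames(qc_log) <- NULL
  attr(g, "qc_log") <- qc_log
  g
}
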