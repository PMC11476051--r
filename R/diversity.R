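#' Per-locus diversity statistics
#'
#' For each marker, over its non-missing calls: allele frequencies, minor
#' allele frequency, observed heterozygosity \eqn{Ho = H_k / n} (share of
#' heterozygous individuals), sample-size-corrected expected heterozygosity
#' \eqn{He = \frac{2n}{2n-1}(1 - \sum_i p_i^2)}, Botstein's polymorphism
#' information content
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}, and the
#' effective allele number \eqn{Ae = 1 / \sum_i p_i^2} (reciprocal expected
#' homozygosity; set `ae_observed = TRUE` for the reciprocal of observed
#' homozygosity instead).
#'
#' @param genotypes a [GenotypeData-class] object or a markers x samples
#'   call matrix.
#' @param ae_observed logical; compute Ae as `1 / (1 - Ho)` rather than
#'   from allele frequencies.
#' @return data.frame with one row per marker: `marker_id`, `n` (non-missing
#'   individuals), `p_alt`, `maf`, `ho`, `he`, `pic`, `ae`. All-missing
#'   markers get `NA` statistics.
#' @export
perLocusStats <- function(genotypes, ae_observed = FALSE) {
  m <- if (methods::is(genotypes, "GenotypeData")) genoCalls(genotypes)
       else genotypes
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(m)))
  n_ok <- rowSums(!is.na(m))
  n_het <- rowSums(m == 1L, na.rm = TRUE)
  p <- altFreq(m)
  q <- 1 - p
  sum_p2 <- p^2 + q^2
  ho <- ifelse(n_ok > 0, n_het / n_ok, NA_real_)
  he <- ifelse(n_ok > 0, (2 * n_ok) / (2 * n_ok - 1) * (1 - sum_p2),
               NA_real_)
  pic <- 1 - sum_p2 - 2 * p^2 * q^2
  ae <- if (ae_observed) 1 / (1 - ho) else 1 / sum_p2
  data.frame(marker_id = ids, n = n_ok, p_alt = p, maf = pmin(p, q),
             ho = ho, he = he, pic = pic, ae = ae, row.names = NULL)
}

#' Polymorphic marker ratio
#'
#' \eqn{P_N = M / N}, the fraction of loci whose minor allele frequency
#' exceeds a polymorphism threshold.
#'
#' @param locus_stats output of [perLocusStats()].
#' @param maf_threshold polymorphism cutoff (default 0.01; strict `>`).
#' @return scalar in \[0, 1\].
#' @export
polymorphicRatio <- function(locus_stats, maf_threshold = 0.01) {
  stopifnot(nrow(locus_stats) >= 1)
  mean(locus_stats$maf > maf_threshold, na.rm = TRUE)
}

#' Population diversity summary with binned distributions
#'
#' Means of the per-locus statistics plus the binned PIC and MAF
#' distributions: PIC bins \[0, 0.15), \[0.15, 0.30), \[0.30, 0.45); MAF
#' bins of width 0.1 on \[0, 0.5\] (right-open, last bin closed).
#'
#' @param locus_stats output of [perLocusStats()].
#' @param maf_threshold passed to [polymorphicRatio()].
#' @return list with `mean_ho`, `mean_he`, `mean_pic`, `mean_ae`,
#'   `mean_maf`, `p_n`, `pic_bins`, `maf_bins` (proportions summing to 1).
#' @export
diversitySummary <- function(locus_stats, maf_threshold = 0.01) {
  ls <- locus_stats[!is.na(locus_stats$ho), ]
  # right-open bins; include.lowest with right = FALSE closes the last bin,
  # so maf exactly 0.5 lands in [0.4, 0.5]
  pic_bins <- table(cut(ls$pic, breaks = c(0, 0.15, 0.30, 0.45),
                        right = FALSE, include.lowest = TRUE))
  maf_bins <- table(cut(ls$maf, breaks = seq(0, 0.5, 0.1),
                        right = FALSE, include.lowest = TRUE))
  list(mean_ho = mean(ls$ho), mean_he = mean(ls$he),
       mean_pic = mean(ls$pic), mean_ae = mean(ls$ae),
       mean_maf = mean(ls$maf),
       p_n = polymorphicRatio(locus_stats, maf_threshold),
       pic_bins = as.numeric(pic_bins) / nrow(ls),
       maf_bins = as.numeric(maf_bins) / nrow(ls))
}

#' Effective population size from linkage disequilibrium
#'
#' Squared genotype correlations \eqn{r^2} are computed between
#' same-chromosome marker pairs, grouped into genetic-distance bins, and
#' inverted through \eqn{Ne = \frac{1}{4c}\left(\frac{1}{r^2} - 1\right)}
#' with \eqn{c} the bin-midpoint distance in Morgans. Before inversion the
#' sample-size correction \eqn{r^2_{adj} = r^2 - 1/(2n)} is applied and
#' floored at `r2_floor`. The summary Ne is the mean over populated bins.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param bin_edges_cM genetic-distance bin edges in cM (default 0.25 to 5
#'   by 0.25).
#' @param sample_size_correction logical; subtract `1/(2n)` from mean r^2.
#' @param r2_floor lower bound applied to adjusted r^2.
#' @return list with `bins` (data.frame `c_mid_cM`, `n_pairs`, `mean_r2`,
#'   `ne`) and `ne_summary`.
#' @export
effectivePopSize <- function(genotypes, bin_edges_cM = seq(0.25, 5, 0.25),
                             sample_size_correction = TRUE,
                             r2_floor = 1e-4) {
  info <- markerInfo(genotypes)
  m <- genoCalls(genotypes)
  n <- ncol(m)
  max_cM <- max(bin_edges_cM)
  r2_all <- c(); d_all <- c()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    if (length(idx) < 2) next
    idx <- idx[order(info$cM[idx])]
    cm <- info$cM[idx]
    x <- t(m[idx, , drop = FALSE])
    x[is.na(x)] <- matrix(colMeans(x, na.rm = TRUE),
                          nrow(x), ncol(x), byrow = TRUE)[is.na(x)]
    sds <- apply(x, 2, stats::sd)
    x <- scale(x)
    M <- length(idx)
    for (lag in seq_len(M - 1)) {
      d <- cm[(1 + lag):M] - cm[1:(M - lag)]
      if (min(d) >= max_cM) break
      sel <- d < max_cM & d >= min(bin_edges_cM) &
        sds[1:(M - lag)] > 0 & sds[(1 + lag):M] > 0
      if (!any(sel)) next
      r <- colSums(x[, 1:(M - lag), drop = FALSE][, sel, drop = FALSE] *
                   x[, (1 + lag):M, drop = FALSE][, sel, drop = FALSE]) /
        (n - 1)
      r2_all <- c(r2_all, r^2)
      d_all <- c(d_all, d[sel])
    }
  }
  if (!length(r2_all)) stop("no same-chromosome marker pairs in range")
  bin <- cut(d_all, breaks = bin_edges_cM, right = FALSE)
  mids <- (bin_edges_cM[-length(bin_edges_cM)] + bin_edges_cM[-1]) / 2
  out <- data.frame(c_mid_cM = mids,
                    n_pairs = as.integer(table(bin)),
                    mean_r2 = as.numeric(tapply(r2_all, bin, mean)))
  empty <- out$n_pairs == 0
  if (any(empty)) warning(sum(empty), " distance bin(s) contain no pairs")
  out <- out[!empty, ]
  r2a <- out$mean_r2
  if (sample_size_correction) r2a <- r2a - 1 / (2 * n)
  r2a <- pmax(r2a, r2_floor)
  c_M <- out$c_mid_cM / 100
  out$ne <- (1 / (4 * c_M)) * (1 / r2a - 1)
  list(bins = out, ne_summary = mean(out$ne))
}
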