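#' Parameters for run-of-homozygosity detection
#'
#' Defaults follow common 50K-chip practice for sheep: 50-SNP scanning
#' window, at most one heterozygous and two missing calls allowed, a minimum
#' of 100 SNPs and 1 Mb per run, marker density of at least one SNP per
#' 50 kb, and a maximum inter-marker gap of 100 kb within a run.
#'
#' @param window_snps scanning window size in SNPs.
#' @param window_threshold a SNP is ROH-eligible when the fraction of
#'   scanning windows overlapping it that qualify exceeds this (strict `>`).
#' @param min_snps minimum SNPs per reported run.
#' @param max_density_kb_per_snp maximum span-per-SNP ratio (kb).
#' @param max_gap_kb runs are split at inter-marker gaps above this.
#' @param max_missing_in_run,max_het_in_run missing / heterozygous call
#'   allowances applied to window qualification (and, when
#'   `final_caps = TRUE`, to the reported segment as a whole).
#' @param min_length_kb minimum run length.
#' @param final_caps logical; if TRUE, a candidate segment whose total
#'   heterozygous or missing count exceeds the allowance is rejected
#'   outright. Off by default: window qualification lets eligibility
#'   extend a few markers into flanking sequence, so long genuine runs
#'   routinely pick up one or two flanking heterozygous calls, and a
#'   whole-segment cap then discards them wholesale, biasing run recovery
#'   and F_ROH downward. Per-segment `n_het`/`n_missing` are always
#'   reported.
#' @return list of class `"rohParams"`.
#' @export
rohParams <- function(window_snps = 50, window_threshold = 0.05,
                      min_snps = 100, max_density_kb_per_snp = 50,
                      max_gap_kb = 100, max_missing_in_run = 2,
                      max_het_in_run = 1, min_length_kb = 1000,
                      final_caps = FALSE) {
  stopifnot(window_snps >= 1, window_threshold >= 0, min_snps >= 1,
            max_density_kb_per_snp > 0, max_gap_kb > 0,
            max_missing_in_run >= 0, max_het_in_run >= 0,
            min_length_kb > 0)
  if (min_snps < window_snps)
    stop("min_snps must be at least window_snps")
  structure(list(window_snps = window_snps,
                 window_threshold = window_threshold, min_snps = min_snps,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 max_missing_in_run = max_missing_in_run,
                 max_het_in_run = max_het_in_run,
                 min_length_kb = min_length_kb,
                 final_caps = isTRUE(final_caps)),
            class = "rohParams")
}

# windowed count of TRUEs: result[s] = sum(x[s:(s+w-1)]) for each window s
.runsum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# per-marker eligibility on one chromosome for one individual
.rohEligible <- function(het, miss, params) {
  M <- length(het)
  w <- params$window_snps
  W <- M - w + 1
  qual <- (.runsum(het, w) <= params$max_het_in_run) &
    (.runsum(miss, w) <= params$max_missing_in_run)
  csq <- c(0, cumsum(qual))
  i <- seq_len(M)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, W)
  n_overlap <- hi - lo + 1L
  n_qual <- csq[hi + 1L] - csq[lo]
  n_qual / n_overlap > params$window_threshold
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: (a) a window of `window_snps` markers
#' slides one marker at a time and qualifies when it contains no more than
#' `max_het_in_run` heterozygous and `max_missing_in_run` missing calls;
#' (b) a marker is ROH-eligible when the fraction of overlapping windows
#' that qualify exceeds `window_threshold`; (c) maximal runs of eligible
#' markers are split at inter-marker gaps above `max_gap_kb` and trimmed so
#' that they start and end on a homozygous, non-missing marker (a run of
#' homozygosity by definition opens and closes with a homozygous call;
#' without trimming, window qualification lets eligibility bleed a few
#' markers into heterozygous flanking sequence); (d) a run is
#' reported iff it has at least `min_snps` markers, spans at least
#' `min_length_kb`, averages at most `max_density_kb_per_snp` per marker,
#' and -- when `final_caps` is set -- itself contains no more than the
#' allowed heterozygous and missing calls.
#'
#' @param genotypes a [GenotypeData-class] object (markers sorted by
#'   position; autosomes only is the caller's responsibility).
#' @param params a [rohParams()] object.
#' @return data.frame of segments: `individual`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb`, `n_het`, `n_missing`.
#' @export
detectROH <- function(genotypes, params = rohParams()) {
  info <- markerInfo(genotypes)
  m <- genoCalls(genotypes)
  ids <- colnames(m)
  out <- list()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    if (length(idx) < params$window_snps) {
      warning("chromosome ", ch, " has fewer markers (", length(idx),
              ") than the scanning window; skipped")
      next
    }
    idx <- idx[order(info$pos_bp[idx])]
    pos <- info$pos_bp[idx]
    gap_after <- c(diff(pos) > params$max_gap_kb * 1000, FALSE)
    for (s in seq_len(ncol(m))) {
      g <- m[idx, s]
      het <- !is.na(g) & g == 1L
      miss <- is.na(g)
      elig <- .rohEligible(het, miss, params)
      segs <- .eligibleRuns(elig, gap_after)
      hom <- !het & !miss
      for (r in segs) {
        k <- r[1]; l <- r[2]
        while (k <= l && !hom[k]) k <- k + 1L
        while (l >= k && !hom[l]) l <- l - 1L
        if (k > l) next
        n_snps <- l - k + 1L
        if (n_snps < params$min_snps) next
        len_bp <- pos[l] - pos[k] + 1
        len_kb <- len_bp / 1000
        if (len_kb < params$min_length_kb) next
        if (len_kb / n_snps > params$max_density_kb_per_snp) next
        nh <- sum(het[k:l]); nm <- sum(miss[k:l])
        if (params$final_caps &&
            (nh > params$max_het_in_run || nm > params$max_missing_in_run))
          next
        out[[length(out) + 1]] <- data.frame(
          individual = ids[s], chrom = ch, start_bp = pos[k],
          end_bp = pos[l], n_snps = n_snps, length_kb = len_kb,
          n_het = nh, n_missing = nm)
      }
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      n_het = integer(), n_missing = integer()))
  do.call(rbind, out)
}

# maximal runs of eligible markers, split where gap_after[i] is TRUE
.eligibleRuns <- function(elig, gap_after) {
  runs <- list()
  start <- NA_integer_
  for (i in seq_along(elig)) {
    if (elig[i] && is.na(start)) start <- i
    if (!is.na(start) && (!elig[i])) {
      runs[[length(runs) + 1]] <- c(start, i - 1L)
      start <- NA_integer_
    } else if (!is.na(start) && gap_after[i]) {
      runs[[length(runs) + 1]] <- c(start, i)
      start <- NA_integer_
    }
  }
  if (!is.na(start))
    runs[[length(runs) + 1]] <- c(start, length(elig))
  runs
}

#' Summarize runs of homozygosity
#'
#' Per-individual counts and total lengths, per-chromosome counts and
#' coverage (union length over chromosome length), length-class counts over
#' the 1-5, 5-10, 10-15, 15-20 and over-20 Mb bins with percentages to two
#' decimals, and F_ROH per individual.
#'
#' @param segments output of [detectROH()].
#' @param genome data.frame with `chrom` and `length_bp` (e.g. from
#'   [chromSpans()], renaming `span_bp`; or a known chromosome-length
#'   table).
#' @param individuals optional full sample-id vector so individuals without
#'   any run appear with zero counts.
#' @return list with `per_individual`, `per_chromosome`, `length_classes`
#'   (`class`, `count`, `percent`), `n_total`, `froh` (named vector),
#'   `froh_mean`, `L_auto`.
#' @export
summarizeROH <- function(segments, genome, individuals = NULL) {
  stopifnot(all(c("chrom", "length_bp") %in% names(genome)))
  if (nrow(segments) && !all(segments$chrom %in% genome$chrom))
    stop("segment on chromosome absent from the genome table: ",
         paste(setdiff(segments$chrom, genome$chrom), collapse = ", "))
  L_auto <- sum(genome$length_bp)
  if (is.null(individuals)) individuals <- unique(segments$individual)
  froh <- fRoh(segments, L_auto, individuals)
  len_mb <- (segments$end_bp - segments$start_bp + 1) / 1e6
  classes <- c("1-5", "5-10", "10-15", "15-20", ">20")
  cls <- cut(len_mb, breaks = c(0, 5, 10, 15, 20, Inf), right = FALSE,
             labels = classes)
  cnt <- as.integer(table(cls))
  n_total <- nrow(segments)
  pct <- if (n_total) round(100 * cnt / n_total, 2) else rep(0, 5)
  per_ind <- data.frame(
    individual = individuals,
    n_roh = as.integer(table(factor(segments$individual,
                                    levels = individuals))),
    total_mb = as.numeric(tapply(len_mb,
                                 factor(segments$individual,
                                        levels = individuals),
                                 sum, default = 0)))
  per_chr <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    sg <- segments[segments$chrom == ch, , drop = FALSE]
    cov <- 0
    if (nrow(sg)) {
      ir <- IRanges::reduce(IRanges::IRanges(sg$start_bp, sg$end_bp))
      cov <- sum(IRanges::width(ir)) / genome$length_bp[i]
    }
    data.frame(chrom = ch, n_roh = nrow(sg), coverage = cov)
  }))
  list(per_individual = per_ind, per_chromosome = per_chr,
       length_classes = data.frame(class = classes, count = cnt,
                                   percent = pct),
       n_total = n_total, froh = froh, froh_mean = mean(froh),
       L_auto = L_auto)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per individual, the summed length of its runs of homozygosity divided by
#' the total autosome length; the population value is the mean over
#' individuals.
#'
#' @param segments output of [detectROH()].
#' @param L_auto total autosome length in bp.
#' @param individuals optional sample ids (individuals without runs get 0).
#' @return named numeric vector of per-individual F_ROH.
#' @export
fRoh <- function(segments, L_auto, individuals = NULL) {
  stopifnot(L_auto > 0)
  if (is.null(individuals)) individuals <- unique(segments$individual)
  len <- segments$end_bp - segments$start_bp + 1
  tot <- tapply(len, factor(segments$individual, levels = individuals),
                sum, default = 0)
  out <- as.numeric(tot) / L_auto
  names(out) <- individuals
  out[is.na(out)] <- 0
  out
}
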