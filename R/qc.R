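#' Exact test of Hardy-Weinberg equilibrium for a biallelic locus
#'
#' Two-sided exact test: conditional on the observed allele counts, all
#' possible heterozygote counts are enumerated (Levene's distribution) and
#' the probabilities of configurations no more likely than the observed one
#' are summed. Probabilities follow the recurrence of the standard SNP exact
#' test, avoiding factorial overflow.
#'
#' @param n_homref,n_het,n_homalt observed genotype counts.
#' @return p-value in \[0, 1\].
#' @examples
#' hweExactPvalue(25, 50, 25)  # Hardy-Weinberg proportions: p = 1
#' @export
hweExactPvalue <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  N <- n_homref + n_het + n_homalt
  if (N < 1) stop("no genotyped individuals at this locus")
  rare <- 2 * min(n_homref, n_homalt) + n_het   # rare allele count
  if (rare == 0) return(1)                      # monomorphic: one config
  hets <- seq(rare %% 2, min(rare, 2 * N - rare), by = 2)
  probs <- numeric(length(hets))
  # start from the largest admissible het count and recurse downward:
  # P(h - 2) / P(h) = h (h - 1) / ((R - h + 2)(2N - R - h + 2))
  i <- length(hets)
  probs[i] <- 1
  h <- hets[i]
  while (i > 1) {
    probs[i - 1] <- probs[i] * h * (h - 1) /
      ((rare - h + 2) * (2 * N - rare - h + 2))
    i <- i - 1
    h <- h - 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Quality-control configuration
#'
#' Defaults mirror common SNP-array practice for livestock panels:
#' minor allele frequency at least 0.05, Hardy-Weinberg exact p above 1e-6,
#' per-marker call rate at least 90%, autosomes 1-26 only, indels dropped.
#'
#' @param maf_min markers with MAF strictly below this are removed.
#' @param hwe_p_min markers with exact-test p strictly below this are
#'   removed.
#' @param geno_max_missing maximum tolerated per-marker missing fraction.
#' @param keep_chromosomes chromosome labels retained.
#' @param drop_indels drop markers whose ref or alt allele is longer than
#'   one base.
#' @return a list of class `"qcConfig"`.
#' @export
qcConfig <- function(maf_min = 0.05, hwe_p_min = 1e-6,
                     geno_max_missing = 0.10,
                     keep_chromosomes = as.character(1:26),
                     drop_indels = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            geno_max_missing >= 0, geno_max_missing < 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 geno_max_missing = geno_max_missing,
                 keep_chromosomes = as.character(keep_chromosomes),
                 drop_indels = drop_indels),
            class = "qcConfig")
}

#' Marker-QC accounting report
#'
#' Holds the bookkeeping of a QC run: total markers in, markers removed per
#' (disjoint) category, and markers retained. `retained` is always
#' `total_in - sum(removed)`; the constructor enforces it, so the report can
#' also replay published QC tables from their printed removal counts.
#'
#' @param total_in total marker count before filtering.
#' @param removed named integer vector of per-category removal counts.
#' @return a list of class `"QCReport"` with elements `total_in`, `removed`,
#'   `retained`.
#' @export
qcReport <- function(total_in, removed) {
  removed <- stats::setNames(as.integer(removed), names(removed))
  stopifnot(total_in >= 0, all(removed >= 0), sum(removed) <= total_in)
  structure(list(total_in = as.integer(total_in), removed = removed,
                 retained = as.integer(total_in - sum(removed))),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("Marker QC report\n")
  cat(sprintf("  total in:   %d\n", x$total_in))
  for (nm in names(x$removed))
    cat(sprintf("  removed %-10s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  cat(sprintf("  retained:   %d\n", x$retained))
  invisible(x)
}

#' Apply marker quality control
#'
#' Filters are applied in a fixed order -- chromosome keep-list, indel drop,
#' call rate, Hardy-Weinberg, minor allele frequency -- and each removed
#' marker is attributed to the first filter that rejects it, so the report
#' categories are disjoint and always sum to `total_in - retained`. MAF and
#' the HWE test use non-missing calls only; an all-missing marker falls to
#' the call-rate filter.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param config a [qcConfig()] object.
#' @return list with `geno` (filtered [GenotypeData-class]) and `report`
#'   (a [qcReport()] object).
#' @export
applyQC <- function(genotypes, config = qcConfig()) {
  stopifnot(nrow(genotypes) > 0)
  info <- markerInfo(genotypes)
  m <- genoCalls(genotypes)
  nmk <- nrow(m); n <- ncol(m)
  category <- rep(NA_character_, nmk)

  off_chrom <- !(info$chrom %in% config$keep_chromosomes)
  category[off_chrom & info$chrom == "X"] <- "chrX"
  category[off_chrom & info$chrom == "Y"] <- "chrY"
  category[off_chrom & is.na(category)] <- "other_chrom"

  if (config$drop_indels) {
    indel <- nchar(info$ref) > 1 | nchar(info$alt) > 1
    category[is.na(category) & indel] <- "indel"
  }

  miss_frac <- rowMeans(is.na(m))
  category[is.na(category) & miss_frac > config$geno_max_missing] <-
    "call_rate"

  todo <- which(is.na(category))
  n_het <- rowSums(m[todo, , drop = FALSE] == 1L, na.rm = TRUE)
  n_alt <- rowSums(m[todo, , drop = FALSE] == 2L, na.rm = TRUE)
  n_ok <- rowSums(!is.na(m[todo, , drop = FALSE]))
  n_ref <- n_ok - n_het - n_alt
  hwe_p <- vapply(seq_along(todo), function(i)
    hweExactPvalue(n_ref[i], n_het[i], n_alt[i]), numeric(1))
  category[todo[hwe_p < config$hwe_p_min]] <- "hwe"

  todo2 <- which(is.na(category))
  p <- altFreq(m[todo2, , drop = FALSE])
  maf <- pmin(p, 1 - p)
  category[todo2[maf < config$maf_min]] <- "maf"

  keep <- is.na(category)
  if (!any(keep))
    stop("no markers survive quality control")
  cats <- c("chrX", "chrY", "other_chrom", "indel", "call_rate", "hwe",
            "maf")
  removed <- vapply(cats, function(cc) sum(category == cc, na.rm = TRUE),
                    integer(1))
  removed <- removed[removed > 0 | names(removed) %in%
                       c("chrX", "chrY", "indel", "call_rate", "hwe", "maf")]
  list(geno = genotypes[keep, ],
       report = qcReport(nmk, removed))
}
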