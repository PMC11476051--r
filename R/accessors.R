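#' Accessors for GenotypeData
#'
#' @param x a [GenotypeData-class] object.
#' @return `genoCalls`: integer matrix markers x samples (0/1/2/NA alt
#'   dosage); `markerInfo`: data.frame of marker metadata; `markerRanges`:
#'   the marker GRanges; `sampleIDs`: character vector; `nMarkers`,
#'   `nSamples`: integer counts.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
genoCalls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname genotype-accessors
#' @export
markerRanges <- function(x) SummarizedExperiment::rowRanges(x)

#' @rdname genotype-accessors
#' @export
markerInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(marker_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos_bp = GenomicRanges::start(rr),
             cM = S4Vectors::mcols(rr)$cM,
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL)
}

#' @rdname genotype-accessors
#' @export
sampleIDs <- function(x) colnames(x)

#' @rdname genotype-accessors
#' @export
nMarkers <- function(x) nrow(x)

#' @rdname genotype-accessors
#' @export
nSamples <- function(x) ncol(x)

#' Alternate-allele frequency per marker
#'
#' Computed over non-missing calls only. Markers with every call missing get
#' `NA`.
#'
#' @param x a [GenotypeData-class] object or a markers x samples call matrix.
#' @return numeric vector of alt-allele frequencies in \[0, 1\].
#' @export
altFreq <- function(x) {
  m <- if (methods::is(x, "GenotypeData")) genoCalls(x) else x
  n_ok <- rowSums(!is.na(m))
  p <- rowSums(m, na.rm = TRUE) / (2 * n_ok)
  p[n_ok == 0] <- NA_real_
  p
}

#' Swap reference and alternate alleles at selected markers
#'
#' Flips genotype codes 0 <-> 2 and exchanges the ref/alt annotation. All
#' downstream statistics in this package are invariant under this operation.
#'
#' @param x a [GenotypeData-class] object.
#' @param at logical or integer index of markers to flip (default: all).
#' @return a [GenotypeData-class] object.
#' @export
swapAlleles <- function(x, at = seq_len(nrow(x))) {
  m <- genoCalls(x)
  m[at, ] <- 2L - m[at, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(x)
  r <- S4Vectors::mcols(rr)$ref
  S4Vectors::mcols(rr)$ref[at] <- S4Vectors::mcols(rr)$alt[at]
  S4Vectors::mcols(rr)$alt[at] <- r[at]
  SummarizedExperiment::rowRanges(x) <- rr
  SummarizedExperiment::assay(x, "calls") <- m
  x
}

#' Observed chromosome spans
#'
#' First-to-last marker position per chromosome; used as the default genome
#' size (e.g. for the total autosome length behind F_ROH) when no chromosome
#' length table is supplied.
#'
#' @param x a [GenotypeData-class] object.
#' @return data.frame with `chrom`, `first_bp`, `last_bp`, `span_bp`.
#' @export
chromSpans <- function(x) {
  info <- markerInfo(x)
  sp <- do.call(rbind, lapply(split(info$pos_bp, info$chrom), range))
  out <- data.frame(chrom = rownames(sp), first_bp = sp[, 1],
                    last_bp = sp[, 2], row.names = NULL)
  out$span_bp <- out$last_bp - out$first_bp + 1
  out[order(suppressWarnings(as.numeric(out$chrom)), out$chrom), ]
}
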