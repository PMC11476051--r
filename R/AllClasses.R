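#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Genotype container for diploid biallelic SNP data
#'
#' \code{GenotypeData} extends \linkS4class{RangedSummarizedExperiment}. The
#' single assay \code{"calls"} is an integer matrix of markers (rows) by
#' samples (columns) holding alt-allele dosages: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, \code{NA} = missing call.
#' Marker metadata live in \code{rowRanges}: chromosome as \code{seqnames}
#' (stored as character labels, \code{"1"}..\code{"26"} for sheep autosomes
#' plus \code{"X"}/\code{"Y"} before quality control), 1-based physical
#' position, and metadata columns \code{cM} (genetic position), \code{ref}
#' and \code{alt} alleles.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}.
#' @seealso [GenotypeData()] for construction, [genoCalls()], [markerInfo()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    if (!is.numeric(m))
      msg <- c(msg, "'calls' must be numeric")
    else {
      bad <- m[!is.na(m)]
      if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
        msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
      msg <- c(msg, "marker ids (rownames) must be present and unique")
    if (!all(c("cM", "ref", "alt") %in% colnames(S4Vectors::mcols(rr))))
      msg <- c(msg, "rowRanges must carry 'cM', 'ref' and 'alt' columns")
    if (any(GenomicRanges::width(rr) != 1L))
      msg <- c(msg, "markers must be width-1 positions")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param calls integer matrix, markers x samples, codes 0/1/2/NA
#'   (alt-allele dosage). Rownames, if set, must match `markers$marker_id`.
#' @param markers data.frame with columns `marker_id`, `chrom` (character),
#'   `pos_bp` (1-based integer), and optionally `cM`, `ref`, `alt`. When `cM`
#'   is absent or zero it is derived as `pos_bp / 1e6` (1 cM per Mb).
#' @param samples character vector of sample ids; defaults to
#'   `colnames(calls)` or `S1..Sn`.
#' @param sort sort markers by chromosome then position (default TRUE).
#'
#' @return a [GenotypeData-class] object.
#' @examples
#' mk <- data.frame(marker_id = c("m1", "m2"), chrom = "1",
#'                  pos_bp = c(100L, 2000L), ref = "A", alt = "G")
#' gd <- GenotypeData(rbind(c(0, 1), c(2, NA)), mk)
#' gd
#' @export
GenotypeData <- function(calls, markers, samples = NULL, sort = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(markers))
  if (is.null(samples))
    samples <- colnames(calls)
  if (is.null(samples))
    samples <- paste0("S", seq_len(ncol(calls)))
  markers$chrom <- as.character(markers$chrom)
  if (is.null(markers$ref)) markers$ref <- "A"
  if (is.null(markers$alt)) markers$alt <- "G"
  cm <- markers$cM
  if (is.null(cm)) cm <- rep(0, nrow(markers))
  cm <- ifelse(is.na(cm) | cm == 0, markers$pos_bp / 1e6, cm)
  rr <- GenomicRanges::GRanges(
    seqnames = markers$chrom,
    ranges = IRanges::IRanges(start = as.integer(markers$pos_bp), width = 1L),
    cM = as.numeric(cm),
    ref = as.character(markers$ref),
    alt = as.character(markers$alt))
  names(rr) <- as.character(markers$marker_id)
  rownames(calls) <- names(rr)
  colnames(calls) <- samples
  gd <- methods::new("GenotypeData",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(calls = calls), rowRanges = rr))
  if (sort) gd <- sortMarkers(gd)
  gd
}

#' @describeIn GenotypeData sort markers by chromosome label then position
#' @param x a GenotypeData object
#' @export
sortMarkers <- function(x) {
  info <- markerInfo(x)
  num <- suppressWarnings(as.numeric(info$chrom))
  key <- ifelse(is.na(num), Inf, num)
  ord <- order(key, info$chrom, info$pos_bp)
  x[ord, ]
}

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "markers x", ncol(object), "samples\n")
  chs <- unique(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object))))
  cat("  chromosomes:", paste(utils::head(chs, 10), collapse = ", "),
      if (length(chs) > 10) "..." else "", "\n")
  m <- SummarizedExperiment::assay(object, "calls")
  cat(sprintf("  missing rate: %.4f\n", mean(is.na(m))))
})
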