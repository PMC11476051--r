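#' Read PLINK 1 text genotypes (.ped/.map)
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param ref_alleles optional named character vector (marker_id -> ref
#'   allele). Without it the first non-missing allele seen at a marker is
#'   taken as the reference; all statistics downstream are invariant to that
#'   orientation, but exact code round-trips need the table.
#' @return a [GenotypeData-class] object.
#' @details `.ped` rows are `FID IID PAT MAT SEX PHENO` followed by two
#'   allele columns per marker; `"0 0"` encodes a missing call. `.map` rows
#'   are `chrom marker_id cM pos_bp`; a zero cM column is replaced by
#'   `pos_bp / 1e6` (1 cM per Mb).
#' @export
readPlink <- function(ped_path, map_path, ref_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "marker_id", "cM", "pos_bp")
  nmk <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  ns <- length(lines)
  calls <- matrix(NA_integer_, nrow = nmk, ncol = ns)
  samples <- character(ns)
  a_ref <- rep(NA_character_, nmk)
  a_alt <- rep(NA_character_, nmk)
  if (!is.null(ref_alleles))
    a_ref <- unname(ref_alleles[map$marker_id])
  for (s in seq_len(ns)) {
    f <- strsplit(trimws(lines[s]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * nmk)
      stop("ragged .ped line ", s, ": expected ", 6 + 2 * nmk,
           " fields, found ", length(f))
    samples[s] <- f[2]
    a1 <- f[seq(7, by = 2, length.out = nmk)]
    a2 <- f[seq(8, by = 2, length.out = nmk)]
    miss <- a1 == "0" | a2 == "0"
    # establish per-marker allele orientation from first-seen alleles
    for (k in which(!miss)) {
      if (is.na(a_ref[k])) a_ref[k] <- a1[k]
      for (al in c(a1[k], a2[k]))
        if (al != a_ref[k]) {
          if (is.na(a_alt[k])) a_alt[k] <- al
          else if (al != a_alt[k])
            stop("marker ", map$marker_id[k], " has more than two alleles")
        }
    }
    code <- (a1 != a_ref) + (a2 != a_ref)
    code[miss] <- NA_integer_
    calls[, s] <- as.integer(code)
  }
  a_alt[is.na(a_alt)] <- "0"   # monomorphic: alt never observed
  map$ref <- ifelse(is.na(a_ref), "0", a_ref)
  map$alt <- a_alt
  GenotypeData(calls, map, samples = samples, sort = FALSE)
}

#' Write PLINK 1 text genotypes (.ped/.map)
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
writePlink <- function(x, prefix) {
  info <- markerInfo(x)
  utils::write.table(info[, c("chrom", "marker_id", "cM", "pos_bp")],
                     paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  m <- genoCalls(x)
  ref <- info$ref; alt <- info$alt
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (s in seq_len(ncol(m))) {
    g <- m[, s]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, alt, ref))
    cat(colnames(m)[s], colnames(m)[s], "0", "0", "0", "-9",
        rbind(a1, a2), "\n", file = con, sep = " ")
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

# 2-bit PLINK codes: 00 hom A1, 01 missing, 10 het, 11 hom A2.
# With the default orientation A1 = alt, A2 = ref this maps to dosages
# 00 -> 2, 01 -> NA, 10 -> 1, 11 -> 0.
.bed_code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)

#' Read PLINK 1 binary genotypes (.bed/.bim/.fam)
#'
#' SNP-major .bed files only (mode byte 0x01). By PLINK convention A1 is the
#' minor allele; by default A1 is mapped to the alternate allele
#' (`a1_is_alt = TRUE`).
#'
#' @param bed,bim,fam file paths.
#' @param a1_is_alt logical; if FALSE, A1 is treated as the reference allele.
#' @return a [GenotypeData-class] object.
#' @export
readPlinkBed <- function(bed, bim, fam, a1_is_alt = TRUE) {
  bm <- utils::read.table(bim, header = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "integer", "character", "character"))
  names(bm) <- c("chrom", "marker_id", "cM", "pos_bp", "A1", "A2")
  fm <- utils::read.table(fam, header = FALSE, colClasses = "character")
  samples <- fm[[2]]
  ns <- length(samples); nmk <- nrow(bm)
  bpm <- ceiling(ns / 4)                  # bytes per marker block
  raw <- readBin(bed, "raw", n = 3 + nmk * bpm)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) < nmk * bpm)
    stop("truncated .bed file at byte offset ", 3 + length(body),
         ": expected ", 3 + nmk * bpm, " bytes")
  ints <- as.integer(body[seq_len(nmk * bpm)])
  # unpack 4 samples per byte, low bits first
  two_bit <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                   (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(two_bit) <- c(4L * bpm, nmk)
  two_bit <- two_bit[seq_len(ns), , drop = FALSE]   # samples x markers
  lut <- c(2L, NA_integer_, 1L, 0L)                 # index = code + 1
  calls <- matrix(lut[two_bit + 1L], nrow = ns)
  calls <- t(calls)
  if (a1_is_alt) { ref <- bm$A2; alt <- bm$A1 }
  else { ref <- bm$A1; alt <- bm$A2; calls <- 2L - calls }
  mk <- data.frame(marker_id = bm$marker_id, chrom = bm$chrom,
                   pos_bp = bm$pos_bp, cM = bm$cM, ref = ref, alt = alt)
  GenotypeData(calls, mk, samples = samples, sort = FALSE)
}

#' Write PLINK 1 binary genotypes (.bed/.bim/.fam)
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix.
#' @param a1_is_alt logical; orientation of the A1 column (see
#'   [readPlinkBed()]).
#' @return invisibly, the three file paths.
#' @export
writePlinkBed <- function(x, prefix, a1_is_alt = TRUE) {
  info <- markerInfo(x)
  if (a1_is_alt) { A1 <- info$alt; A2 <- info$ref }
  else { A1 <- info$ref; A2 <- info$alt }
  utils::write.table(
    data.frame(info$chrom, info$marker_id, info$cM, info$pos_bp, A1, A2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ids <- sampleIDs(x)
  utils::write.table(data.frame(ids, ids, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  m <- genoCalls(x)
  if (!a1_is_alt) m <- 2L - m
  ns <- ncol(m); nmk <- nrow(m); bpm <- ceiling(ns / 4)
  code <- matrix(1L, nrow = 4L * bpm, ncol = nmk)   # 01 = missing padding
  code[seq_len(ns), ] <- ifelse(is.na(t(m)), 1L,
                                .bed_code_from_dosage[as.character(t(m))])
  code[seq_len(ns), ][is.na(t(m))] <- 1L
  bytes <- code[seq(1, 4L * bpm, by = 4), , drop = FALSE] +
    4L * code[seq(2, 4L * bpm, by = 4), , drop = FALSE] +
    16L * code[seq(3, 4L * bpm, by = 4), , drop = FALSE] +
    64L * code[seq(4, 4L * bpm, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read biallelic genotypes from a VCF
#'
#' Uses the GT field only; phased and unphased separators are accepted.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param multiallelic `"error"` (default) or `"drop"` for records with more
#'   than one ALT allele.
#' @return a [GenotypeData-class] object.
#' @export
readGenoVcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (!"GT" %in% unique(unlist(strsplit(v@gt[, 1], ":"))))
    stop("VCF has no GT field")
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic records present (e.g. row ", which(multi)[1], ")")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  mk <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                   pos_bp = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = fix[, "ALT"])
  GenotypeData(code, mk, samples = colnames(gt), sort = FALSE)
}

#' Write genotypes as a VCF 4.2 file
#'
#' @param x a [GenotypeData-class] object.
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writeGenoVcf <- function(x, path) {
  info <- markerInfo(x)
  m <- genoCalls(x)
  gt <- matrix("./.", nrow = nrow(m), ncol = ncol(m))
  gt[m == 0L] <- "0/0"; gt[m == 1L] <- "0/1"; gt[m == 2L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIDs(x)), collapse = "\t")), con)
  body <- cbind(info$chrom, info$pos_bp, info$marker_id, info$ref, info$alt,
                ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (1-based closed, as used throughout this package) plus optional `name`
#'   and `score`, or a GRanges object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBedIntervals <- function(intervals, path) {
  if (methods::is(intervals, "GRanges")) {
    g <- intervals
    intervals <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                            start_bp = GenomicRanges::start(g),
                            end_bp = GenomicRanges::end(g))
    if (!is.null(names(g))) intervals$name <- names(g)
    if ("score" %in% colnames(S4Vectors::mcols(g)))
      intervals$score <- S4Vectors::mcols(g)$score
  }
  out <- data.frame(intervals$chrom, intervals$start_bp - 1L,
                    intervals$end_bp)
  if (!is.null(intervals$name)) {
    out$name <- intervals$name
    out$score <- if (is.null(intervals$score)) 0 else intervals$score
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
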