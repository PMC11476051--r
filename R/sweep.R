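#' Per-marker ROH incidence
#'
#' For every marker, the count and fraction of individuals whose runs of
#' homozygosity cover its position.
#'
#' @param segments output of [detectROH()].
#' @param genotypes the [GenotypeData-class] the segments were called on.
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `count`, `fraction`.
#' @export
snpIncidence <- function(segments, genotypes) {
  info <- markerInfo(genotypes)
  n <- nSamples(genotypes)
  cnt <- integer(nrow(info))
  if (nrow(segments)) {
    segs <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start_bp,
                                                    segments$end_bp))
    mks <- GenomicRanges::GRanges(info$chrom,
                                  IRanges::IRanges(info$pos_bp, width = 1))
    # per-individual runs never overlap, so segment hits = individual hits
    cnt <- GenomicRanges::countOverlaps(mks, segs)
  }
  data.frame(marker_id = info$marker_id, chrom = info$chrom,
             pos_bp = info$pos_bp, count = cnt, fraction = cnt / n)
}

#' ROH islands from top-incidence SNPs
#'
#' Markers whose ROH incidence strictly exceeds the `1 - top_fraction`
#' empirical quantile (type-1, i.e. the order statistic at rank
#' `ceiling((1 - top_fraction) * M)`) are selected, and maximal stretches of
#' consecutive selected markers on a chromosome (no unselected marker in
#' between) are merged into islands spanning their first to last marker.
#'
#' @param segments output of [detectROH()].
#' @param genotypes the [GenotypeData-class] the segments were called on.
#' @param top_fraction upper tail size (default 0.01).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `score`
#'   (mean incidence fraction); attribute `"threshold"` carries the cutoff.
#' @export
rohIslands <- function(segments, genotypes, top_fraction = 0.01) {
  inc <- snpIncidence(segments, genotypes)
  if (all(inc$fraction == 0)) {
    warning("no SNP falls inside any ROH; no islands")
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      score = numeric())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  srt <- sort(inc$fraction)
  thr <- srt[ceiling((1 - top_fraction) * length(srt))]
  sel <- inc$fraction > thr
  out <- list()
  for (ch in unique(inc$chrom)) {
    idx <- which(inc$chrom == ch)
    idx <- idx[order(inc$pos_bp[idx])]
    r <- rle(sel[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      span <- idx[starts[k]:ends[k]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = min(inc$pos_bp[span]),
        end_bp = max(inc$pos_bp[span]), n_snps = length(span),
        score = mean(inc$fraction[span]))
    }
  }
  out <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(), start_bp = integer(),
                         end_bp = integer(), n_snps = integer(),
                         score = numeric())
  attr(out, "threshold") <- thr
  out
}

# sliding windows anchored at position 1; final partial window truncated
.tileWindows <- function(chrom_len, window_bp, step_bp) {
  starts <- seq(1, chrom_len, by = step_bp)
  data.frame(start = starts, end = pmin(starts + window_bp - 1, chrom_len))
}

# per-site allele-count summaries used by the window statistics
.siteCounts <- function(m) {
  n_ok <- rowSums(!is.na(m))
  ca <- rowSums(m, na.rm = TRUE)        # alt allele count
  c_hap <- 2 * n_ok
  cref <- c_hap - ca
  pi_site <- ifelse(c_hap >= 2, 2 * ca * cref / (c_hap * (c_hap - 1)), 0)
  list(c_hap = c_hap, ca = ca, pi_site = pi_site,
       seg = ca > 0 & ca < c_hap & c_hap >= 2)
}

.windowScan <- function(genotypes, window_bp, step_bp, chrom_lengths,
                        fun) {
  info <- markerInfo(genotypes)
  sc <- .siteCounts(genoCalls(genotypes))
  out <- list()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    clen <- if (!is.null(chrom_lengths) && ch %in% chrom_lengths$chrom)
      chrom_lengths$length_bp[match(ch, chrom_lengths$chrom)]
    else max(info$pos_bp[idx])
    w <- .tileWindows(clen, window_bp, step_bp)
    ir_w <- IRanges::IRanges(w$start, w$end)
    ir_s <- IRanges::IRanges(info$pos_bp[idx], width = 1)
    hits <- IRanges::findOverlaps(ir_s, ir_w)
    by_w <- split(idx[S4Vectors::queryHits(hits)],
                  factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(w))))
    res <- lapply(seq_len(nrow(w)), function(i)
      fun(by_w[[i]], w$start[i], w$end[i], sc))
    out[[length(out) + 1]] <- cbind(chrom = ch, w, do.call(rbind, res))
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "start"] <- "start_bp"
  names(res)[names(res) == "end"] <- "end_bp"
  rownames(res) <- NULL
  res
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity \eqn{\pi_s = 2 c_{ref} c_{alt} / (c (c - 1))} with
#' \eqn{c} the non-missing allele count, summed over the variants in each
#' sliding window and divided by the window span in bp.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param window_bp,step_bp window and step size (defaults 100 kb / 10 kb).
#' @param chrom_lengths optional data.frame `chrom`, `length_bp`; windows
#'   are tiled from position 1 to the chromosome end (default: last marker)
#'   and the final partial window is kept, length-normalized.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_variants`, `value`
#'   (pi per bp).
#' @export
windowedPi <- function(genotypes, window_bp = 1e5, step_bp = 1e4,
                       chrom_lengths = NULL) {
  .windowScan(genotypes, window_bp, step_bp, chrom_lengths,
              function(idx, start, end, sc) {
                data.frame(n_variants = length(idx),
                           value = sum(sc$pi_site[idx]) / (end - start + 1))
              })
}

#' Windowed Tajima's D
#'
#' Per window: `S` segregating sites, the summed per-site pairwise
#' difference fraction \eqn{\hat\theta_\pi}, and
#' \deqn{D = \frac{\hat\theta_\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}}
#' with Tajima's constants \eqn{a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2}
#' computed from the haplotype count. Unphased diploids contribute allele
#' counts only; the per-window haplotype count is the modal per-site count
#' (windows where it varies across sites are flagged in `c_varies`). `D` is
#' `NA` when `S = 0`, when fewer than four haplotypes are available, or
#' when the variance term is non-positive.
#'
#' @inheritParams windowedPi
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_variants`, `S`,
#'   `value` (Tajima's D), `n_hap`, `c_varies`.
#' @export
windowedTajimaD <- function(genotypes, window_bp = 1e5, step_bp = 1e4,
                            chrom_lengths = NULL) {
  .windowScan(genotypes, window_bp, step_bp, chrom_lengths,
              function(idx, start, end, sc) {
                use <- idx[sc$c_hap[idx] >= 2]
                S <- sum(sc$seg[use])
                empty <- data.frame(n_variants = length(idx), S = S,
                                    value = NA_real_, n_hap = NA_integer_,
                                    c_varies = FALSE)
                if (S == 0) return(empty)
                ch <- sc$c_hap[use][sc$seg[use]]
                tab <- table(ch)
                n_hap <- as.integer(names(tab)[which.max(tab)])
                empty$n_hap <- n_hap
                empty$c_varies <- length(tab) > 1
                if (n_hap < 4) return(empty)
                pi_sum <- sum(sc$pi_site[use])
                empty$value <- tajimaD(pi_sum, S, n_hap)
                empty
              })
}

#' Tajima's D from summary quantities
#'
#' @param pi_sum mean pairwise differences (summed per-site heterozygosity).
#' @param S number of segregating sites.
#' @param n_hap number of haplotypes.
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimaD <- function(pi_sum, S, n_hap) {
  if (S <= 0 || n_hap < 4) return(NA_real_)
  n <- n_hap
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / a1) / sqrt(v)
}

#' Select candidate regions from windowed statistics
#'
#' Windows whose value lies strictly below the lower `quantile` of the
#' non-missing window values are selected (the classic sweep signature for
#' both low pi and negative Tajima's D); overlapping or book-ended selected
#' windows (gap at most `merge_gap_bp`) merge into regions. With all values
#' equal nothing is selected (strict inequality).
#'
#' @param window_stats output of [windowedPi()] or [windowedTajimaD()].
#' @param method label stored on the result (`"Pi"` or `"TajimaD"`).
#' @param quantile lower-tail size, in (0, 0.5\].
#' @param merge_gap_bp maximum gap between selected windows that still
#'   merges; defaults to the scan's step size (inferred from the window
#'   starts).
#' @return data.frame `method`, `chrom`, `start_bp`, `end_bp`, `n_windows`,
#'   `score` (minimum window value in the region).
#' @export
selectRegions <- function(window_stats, method = c("Pi", "TajimaD"),
                          quantile = 0.01, merge_gap_bp = NULL) {
  method <- match.arg(method)
  if (quantile <= 0 || quantile > 0.5)
    stop("quantile must be in (0, 0.5]")
  ok <- !is.na(window_stats$value)
  thr <- stats::quantile(window_stats$value[ok], quantile, names = FALSE)
  sel <- ok & window_stats$value < thr
  if (is.null(merge_gap_bp)) {
    st <- sort(unique(window_stats$start_bp))
    merge_gap_bp <- if (length(st) > 1) min(diff(st)) else 0
  }
  if (!any(sel))
    return(data.frame(method = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_windows = integer(), score = numeric()))
  ws <- window_stats[sel, ]
  out <- list()
  for (ch in unique(ws$chrom)) {
    sub <- ws[ws$chrom == ch, ]
    ir <- IRanges::IRanges(sub$start_bp, sub$end_bp)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp + 1)
    hit <- IRanges::findOverlaps(ir, red)
    for (k in seq_along(red)) {
      inw <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == k]
      out[[length(out) + 1]] <- data.frame(
        method = method, chrom = ch, start_bp = IRanges::start(red)[k],
        end_bp = IRanges::end(red)[k], n_windows = length(inw),
        score = min(sub$value[inw]))
    }
  }
  do.call(rbind, out)
}

#' Read a gene-interval annotation (BED or GFF3)
#'
#' @param path annotation file. For GFF3, only rows of `feature_type` are
#'   kept and the gene identifier is taken from the first available of
#'   `id_attrs`; for BED the name column is used.
#' @param feature_type GFF3 feature to keep (default `"gene"`).
#' @param id_attrs candidate GFF3 attribute keys for the gene id.
#' @return GRanges with a `gene_id` metadata column.
#' @export
readGeneAnnotation <- function(path, feature_type = "gene",
                               id_attrs = c("gene_id", "ID", "Name")) {
  g <- rtracklayer::import(path)
  md <- S4Vectors::mcols(g)
  if ("type" %in% colnames(md))
    g <- g[as.character(md$type) == feature_type]
  md <- S4Vectors::mcols(g)
  id <- NULL
  for (key in id_attrs)
    if (is.null(id) && key %in% colnames(md)) id <- as.character(md[[key]])
  if (is.null(id) && !is.null(names(g))) id <- names(g)
  if (is.null(id) && "name" %in% colnames(md)) id <- as.character(md$name)
  if (is.null(id)) stop("could not locate gene identifiers in ", path)
  S4Vectors::mcols(g)$gene_id <- id
  g
}

#' Annotate candidate regions with overlapping genes
#'
#' A gene hits a region when their intervals overlap by at least one base
#' (1-based closed coordinates internally; BED half-open input is converted
#' on import, so a gene starting exactly at a region's past-the-end
#' boundary does not hit).
#'
#' @param regions data.frame from [selectRegions()] or [rohIslands()] (needs
#'   `chrom`, `start_bp`, `end_bp`).
#' @param genes GRanges with a `gene_id` column ([readGeneAnnotation()]).
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `gene_id`, one row per
#'   region x gene overlap.
#' @export
annotateRegions <- function(regions, genes) {
  if (!nrow(regions))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), gene_id = character()))
  common <- intersect(unique(regions$chrom),
                      as.character(unique(GenomicRanges::seqnames(genes))))
  if (!length(common) && length(genes))
    stop("no chromosome labels shared between regions and annotation; ",
         "remap the annotation seqnames (e.g. strip a 'chr' prefix)")
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start_bp,
                                               regions$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(r, genes,
                                                       minoverlap = 1))
  data.frame(chrom = regions$chrom[S4Vectors::queryHits(hits)],
             start_bp = regions$start_bp[S4Vectors::queryHits(hits)],
             end_bp = regions$end_bp[S4Vectors::queryHits(hits)],
             gene_id = S4Vectors::mcols(genes)$gene_id[
               S4Vectors::subjectHits(hits)],
             row.names = NULL)
}

#' Intersect candidate gene sets across selection-scan methods
#'
#' @param gene_sets named list of character vectors (one per method, e.g.
#'   `ROH`, `Pi`, `TajimaD`).
#' @return list with `sets` (deduplicated inputs), `venn` (named counts for
#'   every non-empty combination of methods) and `common` (genes found by
#'   all methods).
#' @export
intersectCandidates <- function(gene_sets) {
  sets <- lapply(gene_sets, function(x) sort(unique(as.character(x))))
  nms <- names(sets)
  venn <- list()
  for (k in seq_along(sets))
    for (comb in utils::combn(seq_along(sets), k, simplify = FALSE)) {
      inter <- Reduce(intersect, sets[comb])
      venn[[paste(nms[comb], collapse = "&")]] <- length(inter)
    }
  list(sets = sets, venn = unlist(venn),
       common = Reduce(intersect, sets))
}
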