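# Independent brute-force oracles. Each re-derives a statistic by the most
# literal route available (enumeration, per-locus loops, direct formula
# evaluation) and deliberately shares no code with the package internals.

# small GenotypeData builder
make_gd <- function(calls, chrom = "1", pos = NULL, ref = "A", alt = "G",
                    samples = NULL) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 1000L
  mk <- data.frame(marker_id = paste0("m", seq_len(nrow(calls))),
                   chrom = rep(chrom, length.out = nrow(calls)),
                   pos_bp = pos, ref = ref, alt = alt)
  GenotypeData(calls, mk, samples = samples, sort = FALSE)
}

# random genotype fixture: markers x samples with optional missing calls
rand_calls <- function(n_markers, n_samples, missing_rate = 0) {
  p <- runif(n_markers, 0.05, 0.5)
  m <- matrix(rbinom(n_markers * n_samples, 2, p), nrow = n_markers)
  if (missing_rate > 0)
    m[runif(length(m)) < missing_rate] <- NA_integer_
  m
}

# --- Hardy-Weinberg exact test by closed-form enumeration (log-factorials)
oracle_hwe <- function(nAA, nAB, naa) {
  N <- nAA + nAB + naa
  nA <- 2 * nAA + nAB
  na <- 2 * naa + nAB
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- N - aa - h
    h * log(2) + lfactorial(N) - lfactorial(aa) - lfactorial(h) -
      lfactorial(bb) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * N)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# --- IBS distances by a per-pair per-locus loop
oracle_ibs <- function(m) {
  n <- ncol(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ibs0 <- ibs1 <- ibs2 <- N <- 0
    for (k in seq_len(nrow(m))) {
      a <- m[k, i]; b <- m[k, j]
      if (is.na(a) || is.na(b)) next
      N <- N + 1
      shared <- 2 - abs(a - b)
      if (shared == 2) ibs2 <- ibs2 + 1
      else if (shared == 1) ibs1 <- ibs1 + 1
      else ibs0 <- ibs0 + 1
    }
    D[i, j] <- 1 - (0.5 * ibs1 + ibs2) / N
  }
  D
}

# --- expand unphased genotypes to per-site allele multisets and count
# differing haplotype pairs directly
oracle_pi_sites <- function(m) {
  vapply(seq_len(nrow(m)), function(k) {
    g <- m[k, ]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) switch(as.character(x),
                                                   `0` = c(0, 0),
                                                   `1` = c(0, 1),
                                                   `2` = c(1, 1))))
    c_hap <- length(alleles)
    if (c_hap < 2) return(0)
    diff_pairs <- 0
    for (a in seq_len(c_hap - 1)) for (b in seq((a + 1), c_hap))
      if (alleles[a] != alleles[b]) diff_pairs <- diff_pairs + 1
    diff_pairs / choose(c_hap, 2)
  }, numeric(1))
}

# --- Tajima's D by literal constant-by-constant evaluation on one window
oracle_tajima_window <- function(m) {
  c_hap <- 2 * colSums(!is.na(t(m)))
  pi_s <- oracle_pi_sites(m)
  alt <- rowSums(m, na.rm = TRUE)
  seg <- alt > 0 & alt < c_hap & c_hap >= 2
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  tab <- table(c_hap[seg])
  n <- as.integer(names(tab)[which.max(tab)])
  if (n < 4) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (sum(pi_s) - S / a1) / sqrt(v)
}

# --- literal ROH caller: loops for window qualification, eligibility,
# maximal runs, gap splitting and final filters
oracle_detect_roh <- function(gd, params) {
  info <- markerInfo(gd)
  m <- genoCalls(gd)
  res <- list()
  filt <- function(pos, het, miss, k, l, ids_s, ch) {
    # trim to homozygous non-missing endpoints
    while (k <= l && (het[k] || miss[k])) k <- k + 1
    while (l >= k && (het[l] || miss[l])) l <- l - 1
    if (k > l) return(NULL)
    n_snps <- l - k + 1
    len_kb <- (pos[l] - pos[k] + 1) / 1000
    if (n_snps < params$min_snps) return(NULL)
    if (len_kb < params$min_length_kb) return(NULL)
    if (len_kb / n_snps > params$max_density_kb_per_snp) return(NULL)
    if (isTRUE(params$final_caps)) {
      if (sum(het[k:l]) > params$max_het_in_run) return(NULL)
      if (sum(miss[k:l]) > params$max_missing_in_run) return(NULL)
    }
    data.frame(individual = ids_s, chrom = ch, start_bp = pos[k],
               end_bp = pos[l], n_snps = n_snps, length_kb = len_kb,
               n_het = sum(het[k:l]), n_missing = sum(miss[k:l]))
  }
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    idx <- idx[order(info$pos_bp[idx])]
    M <- length(idx)
    w <- params$window_snps
    if (M < w) next
    pos <- info$pos_bp[idx]
    for (s in seq_len(ncol(m))) {
      g <- m[idx, s]
      het <- !is.na(g) & g == 1
      miss <- is.na(g)
      W <- M - w + 1
      qual <- logical(W)
      for (st in seq_len(W))
        qual[st] <- sum(het[st:(st + w - 1)]) <= params$max_het_in_run &&
          sum(miss[st:(st + w - 1)]) <= params$max_missing_in_run
      elig <- logical(M)
      for (i in seq_len(M)) {
        ws <- max(1, i - w + 1):min(i, W)
        elig[i] <- mean(qual[ws]) > params$window_threshold
      }
      i <- 1
      while (i <= M) {
        if (!elig[i]) { i <- i + 1; next }
        j <- i
        while (j < M && elig[j + 1]) j <- j + 1
        sub <- i
        for (k in i:j) {
          if (k == j || pos[k + 1] - pos[k] > params$max_gap_kb * 1000) {
            res[[length(res) + 1]] <- filt(pos, het, miss, sub, k,
                                           colnames(m)[s], ch)
            sub <- k + 1
          }
        }
        i <- j + 1
      }
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(individual = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      n_het = integer(), n_missing = integer()))
  do.call(rbind, res)
}

# --- ROH islands by rank-and-merge on per-marker incidence counted with an
# explicit loop over segments
oracle_islands <- function(segments, gd, top_fraction = 0.01) {
  info <- markerInfo(gd)
  n <- nSamples(gd)
  frac <- numeric(nrow(info))
  for (k in seq_len(nrow(info))) {
    cnt <- 0
    if (nrow(segments))
      for (r in seq_len(nrow(segments)))
        if (segments$chrom[r] == info$chrom[k] &&
            segments$start_bp[r] <= info$pos_bp[k] &&
            segments$end_bp[r] >= info$pos_bp[k]) cnt <- cnt + 1
    frac[k] <- cnt / n
  }
  thr <- sort(frac)[ceiling((1 - top_fraction) * length(frac))]
  out <- list()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    idx <- idx[order(info$pos_bp[idx])]
    cur <- c()
    for (i in c(idx, NA)) {
      if (!is.na(i) && frac[i] > thr) cur <- c(cur, i)
      else if (length(cur)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start_bp = min(info$pos_bp[cur]),
          end_bp = max(info$pos_bp[cur]), n_snps = length(cur),
          score = mean(frac[cur]))
        cur <- c()
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      score = numeric()))
  do.call(rbind, out)
}

# match two segment tables row-for-row regardless of row order
expect_same_segments <- function(a, b) {
  key <- function(x) {
    if (!nrow(x)) return(character())
    o <- order(x$individual, x$chrom, x$start_bp)
    sprintf("%s|%s|%d|%d|%d|%d|%d", x$individual[o], x$chrom[o],
            x$start_bp[o], x$end_bp[o], x$n_snps[o], x$n_het[o],
            x$n_missing[o])
  }
  expect_identical(key(a), key(b))
}
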