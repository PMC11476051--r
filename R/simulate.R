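#' Simulation configuration
#'
#' Default values emulate a small livestock SNP-array study: ~50 rams in 12
#' half-sib sire lines genotyped on a medium-density chip (26 autosomes,
#' ~50 kb marker spacing), low inbreeding, minor-allele-frequency spectrum
#' roughly uniform.
#'
#' @param n_individuals founder population size.
#' @param n_sire_lines number of paternal half-sib families.
#' @param offspring_range integer range of offspring per sire line.
#' @param dams_per_line number of dams per line; `NA` (default) gives every
#'   offspring its own dam (paternal half-sibs), `1` gives full sibs.
#' @param n_chromosomes,chrom_length_bp autosome count and length.
#' @param marker_spacing_bp mean inter-marker distance (jittered uniformly
#'   between 0.5x and 1.5x).
#' @param maf_spectrum `"uniform"` on `maf_range`, or `"beadchip"`, a binned
#'   spectrum with 21.45% of markers in \[0, 0.1), 17.34% in \[0.1, 0.2) and
#'   the remainder spread evenly over the upper three bins, as reported for
#'   medium-density ovine arrays.
#' @param maf_range numeric length-2, support of the uniform spectrum.
#' @param missing_rate,het_error_rate per-call missing probability and
#'   per-marker heterozygous-error probability inside planted tracts.
#' @param target_F per-individual autozygosity target for
#'   [plantAutozygosity()] (fraction of the autosome in planted tracts).
#' @param planted_roh explicit tracts: data.frame `individual`, `chrom`,
#'   `start_bp`, `length_bp` (alternative to `target_F`).
#' @param tract_length_range_mb planted tract length range (Mb).
#' @param qc_contamination logical; if TRUE, inject marker categories that
#'   quality control must remove (sex-chromosome markers, sub-threshold MAF,
#'   Hardy-Weinberg violations, high missingness, indels) in proportions
#'   mimicking a raw 50K chip report.
#' @param contamination_rates named fractions for the injected categories.
#' @param seed integer RNG seed; every generator output is reproducible
#'   from it.
#' @return a list of class `"simConfig"`.
#' @export
simConfig <- function(n_individuals = 50,
                      n_sire_lines = 12,
                      offspring_range = c(2, 6),
                      dams_per_line = NA,
                      n_chromosomes = 26,
                      chrom_length_bp = 1e8,
                      marker_spacing_bp = 5e4,
                      maf_spectrum = c("uniform", "beadchip"),
                      maf_range = c(0.01, 0.5),
                      missing_rate = 0,
                      het_error_rate = 0,
                      target_F = NULL,
                      planted_roh = NULL,
                      tract_length_range_mb = c(1, 26),
                      qc_contamination = FALSE,
                      contamination_rates = c(maf = 0.0637, hwe = 0.0016,
                                              callrate = 0.0185,
                                              chrX = 0.0236, chrY = 0.0193,
                                              indel = 0.00014),
                      seed = 1L) {
  cfg <- list(n_individuals = n_individuals, n_sire_lines = n_sire_lines,
              offspring_range = offspring_range, dams_per_line = dams_per_line,
              n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
              marker_spacing_bp = marker_spacing_bp,
              maf_spectrum = match.arg(maf_spectrum), maf_range = maf_range,
              missing_rate = missing_rate, het_error_rate = het_error_rate,
              target_F = target_F, planted_roh = planted_roh,
              tract_length_range_mb = tract_length_range_mb,
              qc_contamination = qc_contamination,
              contamination_rates = contamination_rates, seed = seed)
  if (n_chromosomes < 1 || chrom_length_bp < marker_spacing_bp)
    stop("degenerate configuration: no markers would be generated")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  class(cfg) <- "simConfig"
  cfg
}

.drawMaf <- function(n, cfg) {
  if (cfg$maf_spectrum == "uniform")
    return(stats::runif(n, cfg$maf_range[1], cfg$maf_range[2]))
  # 'beadchip': binned spectrum, uniform within bins
  probs <- c(0.2145, 0.1734, rep((1 - 0.2145 - 0.1734) / 3, 3))
  bin <- sample.int(5, n, replace = TRUE, prob = probs)
  lo <- c(cfg$maf_range[1], 0.1, 0.2, 0.3, 0.4)[bin]
  hi <- c(0.1, 0.2, 0.3, 0.4, 0.5)[bin]
  stats::runif(n, lo, hi)
}

.simMarkerMap <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    n_est <- ceiling(cfg$chrom_length_bp / cfg$marker_spacing_bp * 1.2) + 10
    gaps <- stats::runif(n_est, 0.5, 1.5) * cfg$marker_spacing_bp
    pos <- cumsum(gaps)
    pos <- round(pos[pos <= cfg$chrom_length_bp])
    data.frame(chrom = as.character(ch), pos_bp = as.integer(pos))
  })
  mp <- do.call(rbind, maps)
  mp$marker_id <- paste0("snp_", mp$chrom, "_", seq_len(nrow(mp)))
  mp$ref <- "A"; mp$alt <- "G"
  mp[, c("marker_id", "chrom", "pos_bp", "ref", "alt")]
}

#' Simulate an unrelated founder population
#'
#' Marker positions are laid out per chromosome with jittered spacing; each
#' marker's alt-allele frequency is drawn from the configured spectrum and
#' founder haplotypes are sampled independently (Hardy-Weinberg equilibrium
#' holds in expectation).
#'
#' @param config a [simConfig()] object.
#' @return list with `geno` (a [GenotypeData-class]), `truth` (per-marker
#'   true allele frequency and genome table) and `haplos` (two markers x
#'   samples 0/1 haplotype matrices, consumed by [simulateFamilies()]).
#' @export
simulateFounders <- function(config) {
  set.seed(config$seed)
  mp <- .simMarkerMap(config)
  nmk <- nrow(mp); n <- config$n_individuals
  if (nmk == 0) stop("degenerate configuration: no markers generated")
  p <- .drawMaf(nmk, config)
  h1 <- matrix(stats::rbinom(nmk * n, 1, p), nrow = nmk)
  h2 <- matrix(stats::rbinom(nmk * n, 1, p), nrow = nmk)
  truth_cat <- rep("clean", nmk)
  if (config$qc_contamination) {
    cr <- config$contamination_rates
    extra <- .contaminate(mp, n, config)
    mp <- rbind(mp, extra$map)
    h1 <- rbind(h1, extra$h1); h2 <- rbind(h2, extra$h2)
    p <- c(p, extra$p)
    truth_cat <- c(truth_cat, extra$category)
  }
  calls <- h1 + h2
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow = nrow(calls))
    calls[drop] <- NA_integer_
  }
  extra_missing <- which(truth_cat == "callrate")
  if (length(extra_missing)) {
    for (k in extra_missing) {
      rate <- stats::runif(1, 0.15, 0.40)
      calls[k, stats::runif(n) < rate] <- NA_integer_
    }
  }
  samples <- sprintf("F%03d", seq_len(n))
  gd <- GenotypeData(calls, mp, samples = samples, sort = TRUE)
  ord <- match(names(SummarizedExperiment::rowRanges(gd)), mp$marker_id)
  genome <- data.frame(chrom = as.character(seq_len(config$n_chromosomes)),
                       length_bp = config$chrom_length_bp)
  truth <- list(p = p[ord], category = truth_cat[ord], genome = genome,
                family = rep(NA_character_, n))
  list(geno = gd, truth = truth,
       haplos = list(h1 = h1[ord, , drop = FALSE],
                     h2 = h2[ord, , drop = FALSE]))
}

# injected marker categories for exercising the QC accounting
.contaminate <- function(mp, n, config) {
  cr <- config$contamination_rates
  nmk <- nrow(mp)
  counts <- pmax(round(nmk * cr / (1 - sum(cr))), c(1, 1, 1, 1, 1, 1))
  mk <- list(); h1l <- list(); h2l <- list(); pl <- c(); cat <- c()
  add <- function(k, chrom, pos, ref, alt, p, forced_het = FALSE) {
    a <- matrix(stats::rbinom(k * n, 1, rep(p, n)), nrow = k)
    b <- matrix(stats::rbinom(k * n, 1, rep(p, n)), nrow = k)
    if (forced_het) { a[] <- 0L; b[] <- 1L }
    list(map = data.frame(marker_id = character(k), chrom = chrom,
                          pos_bp = pos, ref = ref, alt = alt),
         h1 = a, h2 = b, p = p)
  }
  rpos <- function(k) as.integer(sort(sample.int(config$chrom_length_bp, k)))
  rchrom <- function(k) as.character(sample.int(config$n_chromosomes, k,
                                                replace = TRUE))
  pieces <- list(
    maf = add(counts["maf"], rchrom(counts["maf"]), rpos(counts["maf"]),
              "A", "G", stats::runif(counts["maf"], 0.0005, 0.008)),
    hwe = add(counts["hwe"], rchrom(counts["hwe"]), rpos(counts["hwe"]),
              "A", "G", rep(0.5, counts["hwe"]), forced_het = TRUE),
    callrate = add(counts["callrate"], rchrom(counts["callrate"]),
                   rpos(counts["callrate"]), "A", "G",
                   stats::runif(counts["callrate"], 0.1, 0.5)),
    chrX = add(counts["chrX"], rep("X", counts["chrX"]), rpos(counts["chrX"]),
               "A", "G", stats::runif(counts["chrX"], 0.1, 0.5)),
    chrY = add(counts["chrY"], rep("Y", counts["chrY"]), rpos(counts["chrY"]),
               "A", "G", stats::runif(counts["chrY"], 0.1, 0.5)),
    indel = add(counts["indel"], rchrom(counts["indel"]),
                rpos(counts["indel"]), "A", "AT",
                stats::runif(counts["indel"], 0.1, 0.5)))
  map <- do.call(rbind, lapply(pieces, `[[`, "map"))
  map$marker_id <- paste0("qc_", rep(names(pieces), counts),
                          "_", seq_len(nrow(map)))
  list(map = map,
       h1 = do.call(rbind, lapply(pieces, `[[`, "h1")),
       h2 = do.call(rbind, lapply(pieces, `[[`, "h2")),
       p = unlist(lapply(pieces, `[[`, "p"), use.names = FALSE),
       category = rep(names(pieces), counts))
}

# one gamete from a phased parent: Poisson crossovers at 1 cM/Mb,
# uniform positions, random starting haplotype
.gamete <- function(h1, h2, pos, chrom_index, chrom_length_bp) {
  out <- integer(length(pos))
  for (ch in seq_along(chrom_index)) {
    idx <- chrom_index[[ch]]
    n_xo <- stats::rpois(1, chrom_length_bp / 1e8)
    cuts <- sort(stats::runif(n_xo, 1, chrom_length_bp))
    seg <- findInterval(pos[idx], cuts)
    use1 <- (seg + stats::rbinom(1, 1, 0.5)) %% 2 == 0
    out[idx] <- ifelse(use1, h1[idx], h2[idx])
  }
  out
}

#' Simulate paternal half-sib families from a founder population
#'
#' Each sire line pairs one founder sire with one or more founder dams;
#' offspring genotypes arise by Mendelian gamete sampling with recombination
#' at 1 cM/Mb (Poisson crossover count per chromosome, uniform positions).
#'
#' @param founders output of [simulateFounders()].
#' @param config a [simConfig()] object; `n_sire_lines`, `offspring_range`
#'   and `dams_per_line` control the design.
#' @param include_parents logical; also return the sires (default FALSE).
#' @return list with `geno`, `truth` (with `family` = sire line label per
#'   returned individual) and `haplos`.
#' @export
simulateFamilies <- function(founders, config, include_parents = FALSE) {
  set.seed(config$seed + 1L)
  if (config$n_sire_lines < 1) stop("n_sire_lines must be >= 1")
  if (any(config$offspring_range < 1))
    stop("offspring_range must be positive")
  n_off <- sample(seq(config$offspring_range[1], config$offspring_range[2]),
                  config$n_sire_lines, replace = TRUE)
  dpl <- config$dams_per_line
  n_dams <- if (is.na(dpl)) sum(n_off) else dpl * config$n_sire_lines
  need <- config$n_sire_lines + n_dams
  if (need > ncol(founders$haplos$h1))
    stop("configuration requires ", need, " founders but only ",
         ncol(founders$haplos$h1), " are available")
  info <- markerInfo(founders$geno)
  chrom_index <- split(seq_len(nrow(info)), info$chrom)
  pos <- info$pos_bp
  H1 <- founders$haplos$h1; H2 <- founders$haplos$h2
  dam_pool <- config$n_sire_lines + seq_len(n_dams)
  g1 <- list(); g2 <- list(); fam <- c(); ids <- c()
  d <- 0
  for (line in seq_len(config$n_sire_lines)) {
    for (o in seq_len(n_off[line])) {
      dam <- if (is.na(dpl)) dam_pool[d <- d + 1]
             else dam_pool[(line - 1) * dpl + 1 + (o - 1) %% dpl]
      g1[[length(g1) + 1]] <- .gamete(H1[, line], H2[, line], pos,
                                      chrom_index, config$chrom_length_bp)
      g2[[length(g2) + 1]] <- .gamete(H1[, dam], H2[, dam], pos,
                                      chrom_index, config$chrom_length_bp)
      fam <- c(fam, sprintf("fam%02d", line))
      ids <- c(ids, sprintf("L%02dO%02d", line, o))
    }
  }
  h1 <- do.call(cbind, g1); h2 <- do.call(cbind, g2)
  if (include_parents) {
    sires <- seq_len(config$n_sire_lines)
    h1 <- cbind(H1[, sires], h1); h2 <- cbind(H2[, sires], h2)
    fam <- c(sprintf("fam%02d", sires), fam)
    ids <- c(sprintf("SIRE%02d", sires), ids)
  }
  calls <- h1 + h2
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow = nrow(calls))
    calls[drop] <- NA_integer_
  }
  mk <- info[, c("marker_id", "chrom", "pos_bp", "cM", "ref", "alt")]
  gd <- GenotypeData(calls, mk, samples = ids, sort = FALSE)
  truth <- founders$truth
  truth$family <- stats::setNames(fam, ids)
  list(geno = gd, truth = truth, haplos = list(h1 = h1, h2 = h2))
}

#' Plant autozygous tracts into a genotype matrix
#'
#' Inside each planted tract the individual's genotype is forced homozygous
#' (a heterozygous call is collapsed onto one of its two alleles at random,
#' emulating inheritance of a single haplotype through both parents);
#' `het_error_rate` then re-introduces isolated heterozygous calls to mimic
#' genotyping error. Tracts come either from `config$planted_roh` or are
#' drawn to hit `config$target_F` exactly: lengths uniform on
#' `tract_length_range_mb`, placed without overlap, and the last tract
#' adjusted so the per-individual planted total equals
#' `target_F * L_auto` exactly.
#'
#' @param genotypes a [GenotypeData-class] object or a generator result list
#'   with a `geno` element.
#' @param config a [simConfig()] object.
#' @return list with `geno` and `truth` (`tracts` data.frame and
#'   `autozygosity` = planted fraction per individual).
#' @export
plantAutozygosity <- function(genotypes, config) {
  gd <- if (methods::is(genotypes, "GenotypeData")) genotypes
        else genotypes$geno
  set.seed(config$seed + 2L)
  if (is.null(config$target_F) && is.null(config$planted_roh))
    stop("either target_F or planted_roh must be given")
  info <- markerInfo(gd)
  calls <- genoCalls(gd)
  n <- ncol(calls)
  L_auto <- config$n_chromosomes * config$chrom_length_bp
  tracts <- config$planted_roh
  if (is.null(tracts)) {
    tl <- list()
    for (s in seq_len(n)) {
      total <- config$target_F * L_auto
      placed <- 0
      occupied <- lapply(seq_len(config$n_chromosomes), function(i) NULL)
      while (placed < total - 1) {
        len <- round(stats::runif(1, config$tract_length_range_mb[1],
                                  config$tract_length_range_mb[2]) * 1e6)
        len <- min(len, total - placed)
        # absorb a remainder shorter than the minimum tract length, so no
        # sub-detectable sliver is left over
        if (total - placed - len < config$tract_length_range_mb[1] * 1e6)
          len <- round(total - placed)
        len <- max(len, 2)
        ch <- sample.int(config$n_chromosomes, 1)
        start <- sample.int(config$chrom_length_bp - len, 1)
        iv <- c(start, start + len - 1)
        occ <- occupied[[ch]]
        if (!is.null(occ) &&
            any(iv[1] <= occ[, 2] & iv[2] >= occ[, 1])) next
        occupied[[ch]] <- rbind(occ, iv)
        tl[[length(tl) + 1]] <- data.frame(
          individual = colnames(calls)[s], chrom = as.character(ch),
          start_bp = iv[1], length_bp = len)
        placed <- placed + len
      }
    }
    tracts <- do.call(rbind, tl)
  } else {
    tracts$individual <- as.character(tracts$individual)
    tracts$chrom <- as.character(tracts$chrom)
    ov <- split(tracts, tracts[, c("individual", "chrom")], drop = TRUE)
    for (g in ov) {
      if (nrow(g) < 2) next
      g <- g[order(g$start_bp), ]
      if (any(g$start_bp[-1] <= g$start_bp[-nrow(g)] +
                g$length_bp[-nrow(g)] - 1))
        stop("planted tracts overlap for individual ", g$individual[1])
    }
    if (any(tracts$start_bp + tracts$length_bp - 1 > config$chrom_length_bp))
      stop("planted tract extends beyond its chromosome")
  }
  samp_idx <- stats::setNames(seq_len(n), colnames(calls))
  for (r in seq_len(nrow(tracts))) {
    s <- samp_idx[[tracts$individual[r]]]
    in_tract <- info$chrom == tracts$chrom[r] &
      info$pos_bp >= tracts$start_bp[r] &
      info$pos_bp <= tracts$start_bp[r] + tracts$length_bp[r] - 1
    k <- which(in_tract)
    if (!length(k)) next
    g <- calls[k, s]
    het <- !is.na(g) & g == 1L
    g[het] <- 2L * stats::rbinom(sum(het), 1, 0.5)
    if (config$het_error_rate > 0) {
      err <- stats::runif(length(k)) < config$het_error_rate
      g[err & !is.na(g)] <- 1L
    }
    calls[k, s] <- g
  }
  agg <- tapply(tracts$length_bp, tracts$individual, sum)
  autoz <- stats::setNames(numeric(n), colnames(calls))
  autoz[names(agg)] <- agg / L_auto
  gd2 <- GenotypeData(calls, info, samples = colnames(calls), sort = FALSE)
  list(geno = gd2, truth = list(tracts = tracts, autozygosity = autoz,
                                L_auto = L_auto))
}

#' Simulate neutral-equilibrium windows for Tajima's D calibration
#'
#' Generates independent genomic windows whose site-frequency spectrum
#' follows the neutral infinite-sites expectation (expected number of sites
#' with derived-allele count \eqn{i} proportional to \eqn{1/i}), under which
#' Tajima's D has mean approximately zero. Each window is emitted as its own
#' chromosome so windowed statistics treat them independently. Derived
#' alleles are assigned to haplotypes uniformly at random and paired into
#' unphased diploid genotypes.
#'
#' @param n_windows number of windows.
#' @param n_individuals diploid sample size.
#' @param mean_sites Poisson mean of segregating-site count per window.
#' @param window_bp window span in bp.
#' @param seed RNG seed.
#' @return a [GenotypeData-class] object.
#' @export
simulateNeutralWindows <- function(n_windows, n_individuals,
                                   mean_sites = 20, window_bp = 1e5,
                                   seed = 1L) {
  set.seed(seed)
  c_hap <- 2L * n_individuals
  wts <- 1 / seq_len(c_hap - 1)
  S <- stats::rpois(n_windows, mean_sites)
  total <- sum(S)
  counts <- sample.int(c_hap - 1, total, replace = TRUE, prob = wts)
  win <- rep(seq_len(n_windows), S)
  pos <- as.integer(stats::runif(total, 1, window_bp))
  calls <- matrix(0L, nrow = total, ncol = n_individuals)
  for (j in seq_len(total)) {
    hap <- sample.int(c_hap, counts[j])
    ind <- (hap - 1L) %/% 2L + 1L
    tab <- tabulate(ind, nbins = n_individuals)
    calls[j, ] <- tab
  }
  mk <- data.frame(marker_id = paste0("w", win, "_s", seq_len(total)),
                   chrom = paste0("w", win), pos_bp = pos,
                   ref = "A", alt = "G")
  GenotypeData(calls, mk, samples = sprintf("N%03d", seq_len(n_individuals)),
               sort = TRUE)
}

#' Evolve a closed population by discrete-generation random mating
#'
#' Starts from founder haplotypes and applies `n_generations` of random
#' mating at constant population size (two distinct parents per offspring,
#' gametes recombined at 1 cM/Mb). Used to create populations with
#' drift-equilibrium linkage disequilibrium for effective-population-size
#' estimation.
#'
#' @param founders output of [simulateFounders()].
#' @param config the [simConfig()] used for the founders.
#' @param n_generations number of generations to evolve.
#' @param pop_size population size per generation (default: founder count).
#' @return list with `geno`, `haplos`.
#' @export
simulateRandomMating <- function(founders, config, n_generations,
                                 pop_size = NULL) {
  set.seed(config$seed + 3L)
  info <- markerInfo(founders$geno)
  chrom_index <- split(seq_len(nrow(info)), info$chrom)
  pos <- info$pos_bp
  H1 <- founders$haplos$h1; H2 <- founders$haplos$h2
  if (is.null(pop_size)) pop_size <- ncol(H1)
  for (gen in seq_len(n_generations)) {
    N1 <- matrix(0L, nrow = nrow(H1), ncol = pop_size)
    N2 <- N1
    for (s in seq_len(pop_size)) {
      par <- sample.int(ncol(H1), 2, replace = FALSE)
      N1[, s] <- .gamete(H1[, par[1]], H2[, par[1]], pos, chrom_index,
                         config$chrom_length_bp)
      N2[, s] <- .gamete(H1[, par[2]], H2[, par[2]], pos, chrom_index,
                         config$chrom_length_bp)
    }
    H1 <- N1; H2 <- N2
  }
  calls <- H1 + H2
  mk <- info[, c("marker_id", "chrom", "pos_bp", "cM", "ref", "alt")]
  gd <- GenotypeData(calls, mk,
                     samples = sprintf("G%03d", seq_len(pop_size)),
                     sort = FALSE)
  list(geno = gd, haplos = list(h1 = H1, h2 = H2))
}
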