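# fixture with homozygous stretches planted into a flanking background;
# background = "random" draws HWE genotypes at p = 0.5, "het" makes every
# flanking call heterozygous (sharp, deterministic run boundaries)
roh_fixture <- function(n_markers, n_samples, spacing = 25e3,
                        runs = NULL, seed = 1, background = "random") {
  set.seed(seed)
  pos <- as.integer(seq(spacing, by = spacing, length.out = n_markers))
  m <- if (background == "het") matrix(1L, n_markers, n_samples)
       else matrix(rbinom(n_markers * n_samples, 2, 0.5), nrow = n_markers)
  if (!is.null(runs))
    for (r in seq_len(nrow(runs))) {
      k <- runs$from[r]:runs$to[r]
      m[k, runs$sample[r]] <- 2L * rbinom(length(k), 1, 0.5)
    }
  make_gd(m, pos = pos, samples = paste0("s", seq_len(n_samples)))
}

test_that("detected segments equal the literal brute-force caller", {
  for (seed in 1:8) {
    params <- rohParams(window_snps = 15, window_threshold = 0.05,
                        min_snps = 20, max_density_kb_per_snp = 60,
                        max_gap_kb = 100, min_length_kb = 400,
                        final_caps = seed %% 2 == 0)
    runs <- data.frame(sample = c(1, 2, 2),
                       from = c(30, 10, 120),
                       to = c(90, 45, 170))
    gd <- roh_fixture(200, 3, runs = runs, seed = seed)
    # sprinkle missing calls
    m <- genoCalls(gd)
    m[sample(length(m), 60)] <- NA_integer_
    gd <- make_gd(m, pos = markerInfo(gd)$pos_bp,
                  samples = sampleIDs(gd))
    expect_same_segments(detectROH(gd, params), oracle_detect_roh(gd, params))
  }
})

test_that("a planted clean tract yields exactly one covering segment", {
  # 5 Mb homozygous tract (251 markers at 20 kb) in heterozygous flanks
  gd <- roh_fixture(1000, 1, spacing = 20e3, background = "het",
                    runs = data.frame(sample = 1, from = 400, to = 650),
                    seed = 11)
  segs <- detectROH(gd)
  expect_equal(nrow(segs), 1)
  pos <- markerInfo(gd)$pos_bp
  # covers the tract interior (window-edge erosion is at most one marker)
  expect_lte(segs$start_bp, pos[401])
  expect_gte(segs$end_bp, pos[649])
  expect_same_segments(segs, oracle_detect_roh(gd, rohParams()))
  # the same tract with het-rich random flanks still yields one covering
  # segment, identical to the oracle
  gdr <- roh_fixture(1000, 1, spacing = 20e3,
                     runs = data.frame(sample = 1, from = 400, to = 650),
                     seed = 11)
  segsr <- detectROH(gdr)
  expect_equal(nrow(segsr), 1)
  expect_lte(segsr$start_bp, pos[400])
  expect_gte(segsr$end_bp, pos[650])
  expect_same_segments(segsr, oracle_detect_roh(gdr, rohParams()))
  # two heterozygous calls inside: with the whole-segment cap enforced the
  # tract is rejected outright
  m <- genoCalls(gd)
  m[c(480, 560), 1] <- 1L
  gd2 <- make_gd(m, pos = pos, samples = "s1")
  expect_equal(nrow(detectROH(gd2, rohParams(final_caps = TRUE))), 0)
  # in the default window-level mode the run survives and reports its hets
  segs2 <- detectROH(gd2)
  expect_equal(segs2$n_het, 2L)
  # clustered hets disqualify every window over the run's midsection and
  # split it below min_snps even without the whole-segment cap
  gd3 <- roh_fixture(1000, 1, spacing = 20e3, background = "het",
                     runs = data.frame(sample = 1, from = 450, to = 600),
                     seed = 11)
  m3 <- genoCalls(gd3)
  m3[c(500, 525, 550), 1] <- 1L
  expect_equal(nrow(detectROH(make_gd(m3, pos = pos, samples = "s1"))), 0)
})

test_that("runs below the SNP-count threshold are not called", {
  # 99 homozygous markers cannot satisfy min_snps = 100
  gd <- roh_fixture(400, 1, spacing = 15e3, background = "het",
                    runs = data.frame(sample = 1, from = 150, to = 248),
                    seed = 12)
  expect_equal(nrow(detectROH(gd)), 0)
  # widening the same tract to ~130 markers produces a call
  gd2 <- roh_fixture(400, 1, spacing = 15e3, background = "het",
                     runs = data.frame(sample = 1, from = 140, to = 270),
                     seed = 12)
  segs <- detectROH(gd2)
  expect_equal(nrow(segs), 1)
  expect_gte(segs$n_snps, 100)
})

test_that("runs split at large gaps before filtering", {
  set.seed(13)
  pos <- as.integer(seq(25e3, by = 25e3, length.out = 300))
  pos[151:300] <- pos[151:300] + 500e3          # 525 kb gap at marker 150
  m <- matrix(rbinom(300, 2, 0.5), ncol = 1)
  m[51:250, 1] <- 2L * rbinom(200, 1, 0.5)      # homozygous across the gap
  gd <- make_gd(m, pos = pos, samples = "s1")
  params <- rohParams(window_snps = 20, min_snps = 40, min_length_kb = 800)
  segs <- detectROH(gd, params)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$end_bp <= pos[150] | segs$start_bp >= pos[151]))
  expect_same_segments(segs, oracle_detect_roh(gd, params))
})

test_that("tightening the length threshold never adds segments", {
  gd <- roh_fixture(600, 2, spacing = 30e3,
                    runs = data.frame(sample = c(1, 1, 2),
                                      from = c(50, 300, 100),
                                      to = c(160, 420, 350)),
                    seed = 14)
  lens <- c(500, 1000, 2000, 4000, 8000)
  counts <- vapply(lens, function(L)
    nrow(detectROH(gd, rohParams(window_snps = 20, min_snps = 30,
                                 min_length_kb = L))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("chromosomes shorter than the window are skipped with a warning", {
  gd <- make_gd(matrix(0L, nrow = 10, ncol = 1),
                pos = seq(1e5, 1e6, 1e5))
  expect_warning(segs <- detectROH(gd), "fewer markers")
  expect_equal(nrow(segs), 0)
})

test_that("F_ROH is the exact length ratio and summaries bin correctly", {
  segs <- data.frame(individual = c("a", "a", "b"),
                     chrom = c("1", "2", "1"),
                     start_bp = c(1, 1, 1),
                     end_bp = c(20e6, 5e6, 26e6),
                     n_snps = c(400, 100, 520),
                     length_kb = c(2e4, 5e3, 2.6e4),
                     n_het = 0L, n_missing = 0L)
  fr <- fRoh(segs, L_auto = 2.5e9, individuals = c("a", "b", "c"))
  expect_equal(unname(fr["a"]), 25e6 / 2.5e9)   # 0.01
  expect_equal(unname(fr["c"]), 0)
  genome <- data.frame(chrom = c("1", "2"), length_bp = c(30e6, 30e6))
  sm <- summarizeROH(segs, genome, individuals = c("a", "b", "c"))
  # right-open bins: the 5 Mb segment falls in [5,10), 20 and 26 Mb in >=20
  expect_equal(sm$length_classes$count, c(0L, 1L, 0L, 0L, 2L))
  expect_equal(sum(sm$length_classes$count), sm$n_total)
  expect_equal(sm$per_chromosome$coverage[1], (20e6 + 26e6 - 20e6) / 30e6)
  expect_error(summarizeROH(segs, data.frame(chrom = "1",
                                             length_bp = 30e6)),
               "absent")
  # empty segment set: all zeros
  empty <- segs[0, ]
  sm0 <- summarizeROH(empty, genome, individuals = "a")
  expect_equal(sm0$n_total, 0)
  expect_equal(unname(sm0$froh), 0)
})

test_that("planted tracts >= 2 Mb are recovered with high precision and recall", {
  params <- rohParams(window_snps = 25, window_threshold = 0.05,
                      min_snps = 35, max_density_kb_per_snp = 60,
                      max_gap_kb = 150, min_length_kb = 1000)
  tp <- 0; fn <- 0; fp <- 0
  for (seed in 1:20) {
    cfg <- simConfig(n_individuals = 5, n_chromosomes = 2,
                     chrom_length_bp = 3e7, marker_spacing_bp = 5e4,
                     tract_length_range_mb = c(2, 8), target_F = 0.2,
                     seed = 1000 + seed)
    pl <- plantAutozygosity(simulateFounders(cfg), cfg)
    segs <- detectROH(pl$geno, params)
    tr <- pl$truth$tracts
    tr$end_bp <- tr$start_bp + tr$length_bp - 1
    for (r in seq_len(nrow(tr))) {
      hit <- segs$individual == tr$individual[r] &
        segs$chrom == tr$chrom[r] &
        pmin(segs$end_bp, tr$end_bp[r]) -
          pmax(segs$start_bp, tr$start_bp[r]) >= 0.8 * tr$length_bp[r]
      if (any(hit)) tp <- tp + 1 else fn <- fn + 1
    }
    for (r in seq_len(nrow(segs))) {
      seg_len <- segs$end_bp[r] - segs$start_bp[r] + 1
      hit <- tr$individual == segs$individual[r] &
        tr$chrom == segs$chrom[r] &
        pmin(tr$end_bp, segs$end_bp[r]) -
          pmax(tr$start_bp, segs$start_bp[r]) >= 0.8 * seg_len
      if (!any(hit)) fp <- fp + 1
    }
  }
  expect_gte(tp / (tp + fn), 0.95)   # recall
  expect_gte(tp / (tp + fp), 0.95)   # precision
})
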