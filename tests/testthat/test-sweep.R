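test_that("windowed pi equals all-pairs haplotype difference counting", {
  set.seed(501)
  for (rep in 1:6) {
    n_ind <- sample(3:10, 1)               # up to 20 haplotypes
    m <- rand_calls(50, n_ind, missing_rate = 0.1)
    gd <- make_gd(m, pos = sort(sample.int(5e4, 50)))
    res <- windowedPi(gd, window_bp = 5e4, step_bp = 5e4,
                      chrom_lengths = data.frame(chrom = "1",
                                                 length_bp = 5e4))
    expect_equal(nrow(res), 1)
    expect_equal(res$value, sum(oracle_pi_sites(m)) / 5e4,
                 tolerance = 1e-12)
  }
})

test_that("per-site pi evaluates the unbiased pairwise-difference formula", {
  # one variant, 5 ref / 5 alt alleles of 10: pi_site = 50/90
  m <- matrix(c(0L, 1L, 1L, 1L, 2L), nrow = 1)
  gd <- make_gd(m, pos = 5e4)
  res <- windowedPi(gd, window_bp = 1e5, step_bp = 1e5,
                    chrom_lengths = data.frame(chrom = "1",
                                               length_bp = 1e5))
  expect_equal(res$value, (2 * 5 * 5 / (10 * 9)) / 1e5, tolerance = 1e-12)
  # monomorphic window
  expect_equal(windowedPi(make_gd(matrix(0L, 2, 4)),
                          window_bp = 1e5, step_bp = 1e5)$value, 0)
})

test_that("duplicating every individual rescales pi by 2(c-1)/(2c-1)", {
  set.seed(502)
  m <- rand_calls(40, 6)
  gd1 <- make_gd(m, pos = sort(sample.int(9e4, 40)))
  gd2 <- make_gd(cbind(m, m), pos = markerInfo(gd1)$pos_bp)
  p1 <- windowedPi(gd1, 1e5, 1e5)$value
  p2 <- windowedPi(gd2, 1e5, 1e5)$value
  c_hap <- 12
  expect_equal(p2, p1 * 2 * (c_hap - 1) / (2 * c_hap - 1),
               tolerance = 1e-12)
})

test_that("windowed Tajima's D equals literal constant-by-constant evaluation", {
  set.seed(503)
  for (rep in 1:6) {
    n_ind <- sample(3:12, 1)
    m <- rand_calls(40, n_ind)
    gd <- make_gd(m, pos = sort(sample.int(9e4, 40)))
    res <- windowedTajimaD(gd, window_bp = 1e5, step_bp = 1e5)
    expect_equal(res$value, oracle_tajima_window(m), tolerance = 1e-9)
    expect_equal(res$S, sum(apply(m, 1, function(g) {
      g <- g[!is.na(g)]
      s <- sum(g)
      s > 0 && s < 2 * length(g)
    })))
  }
  # four-haplotype fixture with S = 3, checkable by hand
  m4 <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 1L))
  gd4 <- make_gd(m4, pos = c(100, 200, 300))
  d4 <- windowedTajimaD(gd4, window_bp = 1e3, step_bp = 1e3)
  expect_equal(d4$value, oracle_tajima_window(m4), tolerance = 1e-12)
  expect_equal(d4$S, 3)
  # no segregating sites: D undefined
  d0 <- windowedTajimaD(make_gd(matrix(2L, 3, 4)), 1e5, 1e5)
  expect_true(is.na(d0$value))
  expect_equal(d0$S, 0)
})

test_that("ROH islands merge top-incidence markers and match the oracle", {
  pos <- as.integer(seq(1e4, 1e6, 1e4))                 # 100 markers
  gd <- make_gd(matrix(0L, 100, 20), pos = pos,
                samples = paste0("i", 1:20))
  seg <- function(ind, from, to)
    data.frame(individual = ind, chrom = "1", start_bp = pos[from],
               end_bp = pos[to], n_snps = to - from + 1,
               length_kb = (pos[to] - pos[from] + 1) / 1000,
               n_het = 0L, n_missing = 0L)
  # one shared plateau: markers 40..45 covered by 15/20 individuals; the
  # 92nd order statistic sits in the zero background, so the strict-
  # inequality rule selects exactly the plateau
  segs <- do.call(rbind, lapply(paste0("i", 1:15), seg, from = 40, to = 45))
  isl <- rohIslands(segs, gd, top_fraction = 0.08)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start_bp, isl$end_bp), c(pos[40], pos[45]))
  # a below-threshold marker between two plateaus splits the island in two
  segs2 <- rbind(do.call(rbind, lapply(paste0("i", 1:15), seg, 40, 42)),
                 do.call(rbind, lapply(paste0("i", 1:15), seg, 44, 46)))
  isl2 <- rohIslands(segs2, gd, top_fraction = 0.08)
  expect_equal(nrow(isl2), 2)
  # random segment sets agree with the rank-and-merge oracle
  set.seed(504)
  for (rep in 1:5) {
    rs <- do.call(rbind, lapply(seq_len(30), function(k) {
      from <- sample(1:90, 1); to <- min(100, from + sample(1:10, 1))
      seg(paste0("i", sample(1:20, 1)), from, to)
    }))
    expect_equal(rohIslands(rs, gd, top_fraction = 0.03),
                 oracle_islands(rs, gd, top_fraction = 0.03),
                 ignore_attr = TRUE)
  }
})

test_that("region selection takes the strict lower tail and merges windows", {
  ws <- data.frame(chrom = "1", start_bp = seq(1, 991, 10),
                   end_bp = seq(100, 1090, 10), n_variants = 5,
                   value = rep(1, 100))
  # all equal: nothing selected under strict inequality
  expect_equal(nrow(selectRegions(ws, "Pi", quantile = 0.5)), 0)
  # one window far below the rest: exactly one region
  ws$value[37] <- 1e-6
  r <- selectRegions(ws, "Pi", quantile = 0.05)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start_bp, r$end_bp), c(ws$start_bp[37], ws$end_bp[37]))
  # shrinking the quantile never selects more
  ws$value <- rev(seq_len(100))
  n_sel <- vapply(c(0.3, 0.2, 0.1, 0.05),
                  function(q) sum(selectRegions(ws, "Pi", q)$n_windows),
                  numeric(1))
  expect_true(all(diff(n_sel) <= 0))
  expect_error(selectRegions(ws, "Pi", quantile = 0.7), "quantile")
})

test_that("planted diversity troughs are recovered as selected regions", {
  jac <- numeric(10)
  for (seed in 1:10) {
    cfg <- simConfig(n_individuals = 30, n_chromosomes = 2,
                     chrom_length_bp = 5e7, marker_spacing_bp = 2e4,
                     maf_range = c(0.05, 0.5), seed = 600 + seed)
    f <- simulateFounders(cfg)
    m <- genoCalls(f$geno)
    info <- markerInfo(f$geno)
    # push a 1.2 Mb stretch of chromosome 1 to near-fixation
    trough <- info$chrom == "1" & info$pos_bp >= 2e7 &
      info$pos_bp < 2.12e7
    m[trough, ] <- matrix(rbinom(sum(trough) * 30, 2, 0.01),
                          ncol = 30)
    gd <- make_gd(m, chrom = info$chrom, pos = info$pos_bp)
    pi <- windowedPi(gd)
    regions <- selectRegions(pi, "Pi", quantile = 0.01)
    sel <- regions[regions$chrom == "1", ]
    inter <- sum(pmax(0, pmin(sel$end_bp, 2.12e7) -
                        pmax(sel$start_bp, 2e7) + 1))
    uni <- 1.2e6 + sum(sel$end_bp - sel$start_bp + 1) - inter
    jac[seed] <- inter / uni
  }
  expect_gte(mean(jac), 0.5)
})

test_that("gene annotation uses half-open BED arithmetic and intersects sets", {
  dir <- tempdir()
  # region 1:1000-2000 (1-based closed); a BED gene starting at 0-based 2000
  # abuts it and must not hit
  writeLines(c("1\t2000\t2500\tabut\t0\t+",
               "1\t1500\t1600\tinside\t0\t+",
               "2\t100\t200\telsewhere\t0\t+"),
             file.path(dir, "genes.bed"))
  genes <- readGeneAnnotation(file.path(dir, "genes.bed"))
  hits <- annotateRegions(data.frame(chrom = "1", start_bp = 1000L,
                                     end_bp = 2000L), genes)
  expect_identical(hits$gene_id, "inside")
  # chromosome naming mismatch is a hard error with a hint
  writeLines("chr9\t100\t200\tg\t0\t+", file.path(dir, "wrong.bed"))
  expect_error(annotateRegions(data.frame(chrom = "1", start_bp = 1L,
                                          end_bp = 10L),
                               readGeneAnnotation(file.path(dir,
                                                            "wrong.bed"))),
               "remap")
  # empty annotation: empty gene sets and zero Venn counts
  empty_hits <- annotateRegions(data.frame(chrom = character(),
                                           start_bp = integer(),
                                           end_bp = integer()), genes)
  expect_equal(nrow(empty_hits), 0)
  vn <- intersectCandidates(list(ROH = character(), Pi = character(),
                                 TajimaD = character()))
  expect_true(all(vn$venn == 0))
})

test_that("three-way intersection recovers genes planted in all methods", {
  sets <- list(ROH = c("g1", "g2", "shared1", "shared2"),
               Pi = c("g3", "shared1", "shared2", "pi_only"),
               TajimaD = c("shared1", "shared2", "g4"))
  res <- intersectCandidates(sets)
  expect_setequal(res$common, c("shared1", "shared2"))
  # inclusion-exclusion over the union
  v <- res$venn
  union_size <- length(unique(unlist(sets)))
  expect_equal(v[["ROH"]] + v[["Pi"]] + v[["TajimaD"]] -
                 v[["ROH&Pi"]] - v[["ROH&TajimaD"]] - v[["Pi&TajimaD"]] +
                 v[["ROH&Pi&TajimaD"]], union_size)
})

test_that("GFF3 gene annotation is filtered by feature type", {
  dir <- tempdir()
  writeLines(c("##gff-version 3",
               paste("1", "src", "gene", "1500", "1600", ".", "+", ".",
                     "ID=gene:G1;Name=MYGENE", sep = "\t"),
               paste("1", "src", "exon", "1500", "1550", ".", "+", ".",
                     "ID=exon:E1", sep = "\t")),
             file.path(dir, "genes.gff3"))
  genes <- readGeneAnnotation(file.path(dir, "genes.gff3"),
                              id_attrs = "Name")
  expect_equal(length(genes), 1)
  hits <- annotateRegions(data.frame(chrom = "1", start_bp = 1000L,
                                     end_bp = 2000L), genes)
  expect_identical(hits$gene_id, "MYGENE")
})
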