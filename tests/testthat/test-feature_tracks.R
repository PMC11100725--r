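test_that("coverage over intervals is exact on constructed tracks", {
  loci <- mk_loci(3, spacing = 1e6)
  # constant track over everything: every SE gets v * 15000
  const <- genomic_track(data.table(chrom = "chr1", start = 0, end = 2e8,
                                    value = 2.5))
  expect_equal(coverage_over_intervals(const, loci), rep(2.5 * 15000, 3))

  # box signals matching each SE exactly are recovered; absent overlap = 0
  box <- genomic_track(data.table(chrom = "chr1",
                                  start = loci$start[1:2],
                                  end = loci$end[1:2], value = c(4, 9)))
  expect_equal(coverage_over_intervals(box, loci),
               c(4 * 15000, 9 * 15000, 0))

  # linearity in the track values
  box2 <- genomic_track(data.table(chrom = "chr1", start = loci$start[1:2],
                                   end = loci$end[1:2], value = 3 * c(4, 9)))
  expect_equal(coverage_over_intervals(box2, loci),
               3 * coverage_over_intervals(box, loci))

  # partial overlap is weighted by overlap length
  half <- genomic_track(data.table(chrom = "chr1", start = loci$start[1],
                                   end = loci$start[1] + 7500, value = 2))
  expect_equal(coverage_over_intervals(half, loci), c(2 * 7500, 0, 0))

  # normalization scales by total signal
  nrm <- coverage_over_intervals(box, loci, normalize = TRUE)
  total <- 4 * 15000 + 9 * 15000
  expect_equal(nrm[1], 4 * 15000 / total * 1e6)

  # genome-build mismatch is refused
  tr_h <- genomic_track(data.table(chrom = "chr1", start = 0, end = 1e6,
                                   value = 1), genome_build = "hg38")
  lo2 <- mk_loci(2)
  data.table::setattr(lo2, "genome_build", "mm10")
  expect_error(coverage_over_intervals(tr_h, lo2), "build mismatch")
})

test_that("DamID window score averages the anchor-bin neighborhood", {
  # 10 kb bins with a step function
  bins <- genomic_track(data.table(chrom = "chr1",
                                   start = seq(0, 9e4, 1e4),
                                   end = seq(1e4, 1e5, 1e4),
                                   value = c(0, 0, 0, 1, 5, 1, 0, 0, 0, 0)))
  # SE inside bin 5 (40-50 kb): mean of bins 4,5,6 = (1+5+1)/3
  se_mid <- se_locus_table(data.table(chrom = "chr1", start = 42000,
                                      end = 47000, name = "mid"))
  expect_equal(damid_window_score(bins, se_mid), (1 + 5 + 1) / 3)

  # SE straddling bins 4 (40%) and 5 (60%): the 60% bin anchors the window
  se_str <- se_locus_table(data.table(chrom = "chr1", start = 36000,
                                      end = 46000, name = "straddle"))
  expect_equal(damid_window_score(bins, se_str), (1 + 5 + 1) / 3)
  # flipped proportions anchor on bin 4 -> mean of bins 3,4,5 = (0+1+5)/3
  se_str2 <- se_locus_table(data.table(chrom = "chr1", start = 34000,
                                       end = 44000, name = "straddle2"))
  expect_equal(damid_window_score(bins, se_str2), (0 + 1 + 5) / 3)

  # no overlapping bin -> NA with warning (GenomicRanges adds its own
  # seqlevel warnings; assert ours is among them)
  se_out <- se_locus_table(data.table(chrom = "chr9", start = 0, end = 15000,
                                      name = "off"))
  ws <- capture_warnings(v <- damid_window_score(bins, se_out))
  expect_true(any(grepl("without any", ws)))
  expect_true(is.na(v))
})

test_that("speckle association filters clusters and bins unique reads", {
  lines <- c(
    "bc1\tMalat1,Xist\tchr1:100,chr1:200,chr2:100000",       # kept, 3 reads
    "bc2\tXist\tchr1:300",                                   # no speckle RNA
    paste0("bc3\tU1.snRNA\t",
           paste(sprintf("chr3:%d", 1:150 * 1000), collapse = ",")), # too big
    "bc4\tU2.snRNA\tchr1:150,chr1:150,chr1:400000")          # dup read -> 2
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)
  cl <- read_sprite_clusters(path)
  expect_length(cl, 4L)
  bins <- speckle_association(cl, bin = 250000)
  # chr1 bin 0: bc1 gives 2 reads + bc4 gives 1 unique (dup collapsed)
  expect_equal(bins[chrom == "chr1" & bin_start == 0, count], 3L)
  expect_equal(bins[chrom == "chr1" & bin_start == 250000, count], 1L)
  expect_equal(bins[chrom == "chr2", count], 1L)
  expect_false("chr3" %in% bins$chrom)

  # the RNA and size filters commute
  swap <- Filter(function(x) nrow(x$dna) <= 100, cl)
  swap <- Filter(function(x) any(x$rnas %in% c("Malat1", "U1.snRNA",
                                               "U2.snRNA")), swap)
  direct <- speckle_association(cl)
  expect_equal(speckle_association(swap), direct)
  expect_error(speckle_association(list()), "empty")

  # per-SE mapping takes the largest-overlap bin
  loci <- se_locus_table(data.table(chrom = "chr1", start = 240000,
                                    end = 255000, name = "A"))
  # overlaps bin 0 by 10 kb and bin 250000 by 5 kb -> takes bin 0 count
  expect_equal(bin_score_per_locus(bins, loci), 3)
})

test_that("tether metrics match the brute-force definition", {
  lone <- se_locus_table(data.table(chrom = "chrY", start = 0, end = 15000,
                                    name = "lone"))
  tm0 <- tether_metrics(lone)
  expect_equal(tm0$n_se_1mb, 0L)
  expect_equal(tm0$inv_dist_sum, 0)

  pair <- se_locus_table(data.table(chrom = "chr1",
                                    start = c(10e6, 10.5e6) - 7500,
                                    end = c(10e6, 10.5e6) + 7500,
                                    name = c("A", "B")))
  tm <- tether_metrics(pair)
  expect_equal(tm$n_se_1mb, c(1L, 1L))
  expect_equal(tm$inv_dist_sum, c(2, 2))

  # dense cluster fixture vs explicit loop
  set.seed(110)
  centers <- sort(round(runif(10, 50e6, 52e6)))
  clus <- se_locus_table(data.table(chrom = "chr13", start = centers - 7500,
                                    end = centers + 7500,
                                    name = sprintf("H%02d", 1:10)))
  tm2 <- tether_metrics(clus)
  for (i in 1:10) {
    d <- abs(centers[-i] - centers[i])
    expect_equal(tm2$n_se_1mb[i], sum(d <= 1e6))
    expect_equal(tm2$inv_dist_sum[i], sum(1 / (d / 1e6)))
  }
})

test_that("build_feature_table assembles and imputes", {
  loci <- synthetic_locus_table(30, seed = 111)
  set.seed(111)
  dir <- withr::local_tempdir()
  synth_feature_tracks(loci, bedgraph_dir = dir)
  tracks <- list(pol2 = read_bedgraph(file.path(dir, "pol2.bedgraph")),
                 med1 = read_bedgraph(file.path(dir, "med1.bedgraph")))
  starts <- seq(0, 2e8 - 1e5, 1e5)
  damid <- genomic_track(rbindlist(lapply(unique(loci$chrom), function(ch)
    data.table(chrom = ch, start = starts, end = starts + 1e5,
               value = rnorm(length(starts))))))
  suppressWarnings(suppressMessages(ft <- build_feature_table(loci, tracks,
                                                              damid)))
  expect_equal(nrow(ft), sum(!loci$dropped))
  expect_false(anyNA(ft$lad_score))   # off-chromosome loci imputed
  expect_true(all(c("pol2", "med1", "n_se_1mb", "inv_dist_sum") %in% names(ft)))
})
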