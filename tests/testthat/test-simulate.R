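test_that("uniform nucleus sampler matches the analytic radial law", {
  set.seed(60)
  R <- 5000
  pts <- sample_uniform_nucleus(1e5, R)
  r <- sqrt(rowSums(pts^2))
  expect_lte(max(r), R)
  # P(r <= R/2) = (1/2)^3
  expect_equal(mean(r <= R / 2), 1 / 8, tolerance = 0.01)
  # Kolmogorov-Smirnov against F(r) = (r/R)^3
  ks <- suppressWarnings(ks.test(r, function(q) (q / R)^3))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_uniform_nucleus(10, -1), "positive")
})

test_that("generators are bit-reproducible given a seed", {
  loci <- synthetic_locus_table(10, seed = 61)
  cfg <- sim_config(n_cells = 5, n_points = 20)
  set.seed(61); t1 <- simulate_null_cells(cfg, loci)
  set.seed(61); t2 <- simulate_null_cells(cfg, loci)
  expect_identical(t1$spots, t2$spots)
  set.seed(62); t3 <- simulate_territory_cells(loci, cfg)
  set.seed(62); t4 <- simulate_territory_cells(loci, cfg)
  expect_identical(t3$spots, t4$spots)
  expect_identical(synthetic_locus_table(50, seed = 9),
                   synthetic_locus_table(50, seed = 9))
})

test_that("null-model cluster size dilutes with nucleus radius", {
  loci <- synthetic_locus_table(50, seed = 63)
  set.seed(63)
  sizes <- vapply(c(1500, 3000, 6000), function(R) {
    tab <- simulate_null_cells(sim_config(n_cells = 60, n_points = 100,
                                          nucleus_radius = R), loci)
    mean(cluster_size_profile(tab, 200)$per_se$mean_cluster_size)
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
  expect_gt(sizes[1], 1)
  # single point per cell -> every cluster has size exactly 1
  one <- se_locus_table(data.table(chrom = "chr1", start = 0, end = 15000,
                                   name = "A"))
  tab1 <- simulate_null_cells(sim_config(n_cells = 5, n_points = 2), one)
  expect_true(all(cluster_size_profile(tab1, 1)$per_se$mean_cluster_size == 1))
})

test_that("territory model responds to its parameters", {
  loci <- synthetic_locus_table(40, seed = 64)
  # persistence -> 0 collapses cis SEs onto the territory center
  set.seed(64)
  tight <- simulate_territory_cells(loci, sim_config(
    n_cells = 3, persistence_scale = 0, territory_spread = 0))
  d <- pairwise_distance_map(tight, cell_ids(tight)[1])
  cis <- outer(d$se_id, d$se_id, function(a, b)
    loci$chrom[match(a, loci$se_id)] == loci$chrom[match(b, loci$se_id)])
  same_allele <- outer(d$allele, d$allele, "==")
  expect_lt(max(d$d[cis & same_allele & upper.tri(d$d)]), 1e-6)

  # attractor bias raises the community size of high-affinity SEs
  set.seed(65)
  cfg_on <- sim_config(n_cells = 40, attractor_bias = 0.6, n_attractors = 3)
  t_on <- simulate_territory_cells(loci, cfg_on)
  prof <- cluster_size_profile(t_on, 600)
  hi <- loci$se_id[loci$affinity > 0.5]
  lo <- loci$se_id[loci$affinity <= 0.5]
  m <- prof$per_se[, mean(mean_cluster_size), keyby = .(hi = se_id %in% hi)]
  expect_gt(m$V1[m$hi], m$V1[!m$hi])
})

test_that("detection noise has the stated dropout and error structure", {
  loci <- synthetic_locus_table(15, seed = 66)
  set.seed(66)
  tab <- simulate_null_cells(sim_config(n_cells = 200, n_points = 30), loci)
  # eff = 1, sigma = 0 is the identity
  expect_identical(apply_detection_noise(tab, 1, 0)$spots, tab$spots)
  noisy <- apply_detection_noise(tab, 0.9, 60)
  expect_equal(mean(noisy$spots$detected), 0.9, tolerance = 0.01)
  de <- detection_efficiency(noisy)
  expect_equal(median(de$per_se$both_allele_freq), 0.81, tolerance = 0.03)
  # two independent noisings: median displacement equals the MC oracle for
  # the difference of two isotropic errors (per-axis sigma * sqrt(2))
  set.seed(67)
  n1 <- apply_detection_noise(tab, 1, 60)
  n2 <- apply_detection_noise(tab, 1, 60)
  est <- replicate_error(as.matrix(n1$spots[, .(x, y, z)]),
                         as.matrix(n2$spots[, .(x, y, z)]))$median
  oracle <- median(sqrt(rowSums(matrix(rnorm(3e5, sd = sqrt(2) * 60 / sqrt(3)),
                                       ncol = 3)^2)))
  expect_equal(est, oracle, tolerance = 0.05 * oracle)
})

test_that("burst model calibration maps sizes to odds as stated", {
  bm <- burst_model()
  expect_equal(burst_probability(bm, 1), 0.2)
  # delta anchors reproduce the intended odds ratios exactly in expectation
  odds <- function(p) p / (1 - p)
  expect_equal(odds(burst_probability(bm, 3)) / odds(0.2), exp(0.2231),
               tolerance = 1e-12)
  expect_equal(odds(burst_probability(bm, 10)) / odds(0.2), exp(1.0986),
               tolerance = 1e-12)
  expect_error(burst_model(logodds_anchors = c("2" = 0.5)), "anchor")

  # flat model: recovered OR ~ 1; zero baseline: nothing bursts
  set.seed(68)
  flat <- burst_model(logodds_anchors = c("1" = 0))
  rec <- simulate_size_bursts(sample(1:10, 2e4, TRUE), flat)
  or3 <- bursting_odds_by_size(rec, sizes = rec$size)[size == 3, or]
  expect_equal(or3, 1, tolerance = 0.15)
  none <- simulate_size_bursts(1:100, burst_model(baseline_p = 0))
  expect_false(any(none$on))
})

test_that("attach_bursts couples bursting to community size", {
  loci <- synthetic_locus_table(40, seed = 69)
  genes <- data.table(gene = c("Nanog", "Sox2", "Mycn"),
                      se_id = loci[name %in% c("Nanog-0", "Sox2-0", "Mycn-0"),
                                   se_id])
  set.seed(69)
  tab <- simulate_territory_cells(loci, sim_config(n_cells = 50))
  rec <- attach_bursts(tab, genes)
  expect_equal(nrow(rec), 50L * 2L * 3L)
  expect_true(all(rec$intensity[!rec$on] == 0))
  expect_true(all(rec$intensity[rec$on] > 0))
  expect_error(attach_bursts(tab, data.table(gene = "X", se_id = "nope")),
               "absent")
})

test_that("synthetic feature tracks reflect their loadings", {
  loci <- synthetic_locus_table(60, seed = 70)
  set.seed(70)
  # zero noise, loading only on affinity: speckle feature recovers affinity
  ft0 <- synth_feature_tracks(loci, noise_sd = 0, loadings = list(
    tether = c(speckle_score = 0), affinity = c(speckle_score = 1)))
  expect_equal(cor(ft0$speckle_score, loci$affinity, method = "spearman"), 1)
  # bedGraph fixtures are written and readable
  dir <- withr::local_tempdir()
  ft <- synth_feature_tracks(loci, bedgraph_dir = dir)
  expect_true(file.exists(file.path(dir, "pol2.bedgraph")))
  tr <- read_bedgraph(file.path(dir, "pol2.bedgraph"))
  expect_true(nrow(tr) > 0)
})
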