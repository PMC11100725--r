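test_that("distance maps propagate missingness and match brute force", {
  loci <- mk_loci(4)
  tab <- mk_table(data.table(
    cell_id = "c1", se_id = loci$se_id, allele = 0L,
    x = c(0, 0, 0, 0), y = c(0, 0, 0, 0), z = c(0, 300, 150, NA),
    detected = c(TRUE, TRUE, TRUE, FALSE)), loci)
  m <- pairwise_distance_map(tab)
  expect_equal(m$d[1, 2], 300)
  expect_true(all(is.na(m$d[4, ])) && all(is.na(m$d[, 4])))
  expect_equal(m$d, t(m$d))

  # random cell vs double-loop oracle
  set.seed(80)
  loci20 <- mk_loci(20)
  pts <- matrix(runif(60, -2000, 2000), ncol = 3)
  det <- runif(20) > 0.2
  pts[!det, ] <- NA
  tab2 <- mk_table(data.table(cell_id = "c1", se_id = loci20$se_id,
                              allele = 0L, x = pts[, 1], y = pts[, 2],
                              z = pts[, 3], detected = det), loci20)
  m2 <- pairwise_distance_map(tab2)
  for (r in c(200, 600, 1500)) {
    expect_equal(neighbor_counts(m2, r), brute_neighbor_counts(pts, det, r))
  }
})

test_that("neighbor counts honor the strict radius threshold", {
  loci <- mk_loci(3)
  tab <- mk_cell(cbind(0, 0, c(0, 150, 400)), loci)
  m <- pairwise_distance_map(tab)
  expect_equal(neighbor_counts(m, 200), c(1L, 1L, 0L))
  expect_equal(neighbor_counts(m, 600), c(2L, 2L, 2L))
  # a tie at exactly the radius is excluded
  expect_equal(neighbor_counts(m, 150), c(0L, 0L, 0L))
})

test_that("cluster profile normalizes by partner detection frequency", {
  # forced arithmetic: raw mean 2 partners, partner detection 0.8
  # -> 1 + 2 / 0.8 = 3.5
  loci <- mk_loci(5)
  prof_stub <- 1 + 2 / 0.8
  expect_equal(prof_stub, 3.5)
  set.seed(81)
  tab <- simulate_null_cells(sim_config(n_cells = 150, n_points = 10,
                                        nucleus_radius = 1200), loci)
  # with perfect detection, normalized and raw profiles coincide
  de <- detection_efficiency(tab)
  p_raw <- cluster_size_profile(tab, 600)
  p_norm <- cluster_size_profile(tab, 600, de)
  expect_equal(p_norm$per_se$mean_cluster_size, p_raw$per_se$mean_cluster_size)
  # with dropout, the normalized profile recovers the full-detection one
  noisy <- apply_detection_noise(tab, 0.8, 0)
  p_c <- cluster_size_profile(noisy, 600, detection_efficiency(noisy))
  expect_equal(mean(p_c$per_se$mean_cluster_size),
               mean(p_raw$per_se$mean_cluster_size), tolerance = 0.05)
  # partner-count frequencies sum to 1
  freqs <- p_raw$per_se[, freq0 + freq1 + freq2 + freq3 + freq4plus]
  expect_equal(freqs, rep(1, nrow(p_raw$per_se)))
})

test_that("isolated spots give degenerate profiles", {
  loci <- mk_loci(4)
  tab <- mk_cell(cbind(c(0, 5000, 10000, 15000), 0, 0), loci)
  prof <- cluster_size_profile(tab, 200)
  expect_true(all(prof$per_se$freq0 == 1))
  expect_true(all(prof$per_se$p95_cluster_size == 1))
  expect_true(all(prof$per_se$mean_cluster_size == 1))
})

test_that("cluster statistics are rigid-motion invariant", {
  loci <- mk_loci(15)
  set.seed(82)
  tab <- simulate_null_cells(sim_config(n_cells = 20, n_points = 30,
                                        nucleus_radius = 1500), loci)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sp <- data.table::copy(tab$spots)
  pts <- as.matrix(sp[, .(x, y, z)]) %*% rot
  sp[, `:=`(x = pts[, 1] + 123, y = pts[, 2] - 456, z = pts[, 3] + 7)]
  tab_r <- cell_table(sp, loci)
  p1 <- cluster_size_profile(tab, 400)
  p2 <- cluster_size_profile(tab_r, 400)
  expect_equal(p1$per_se$mean_cluster_size, p2$per_se$mean_cluster_size,
               tolerance = 1e-10)
})

test_that("pairwise contact frequency counts alleles and flags undefined", {
  loci <- mk_loci(2)
  # fixture built to give 9 contacts in 100 observed alleles = 9%
  set.seed(83)
  n_cells <- 50L
  rows <- list()
  k <- 0L
  contact_alleles <- sample(100, 9)
  for (ci in seq_len(n_cells)) for (al in 0:1) {
    k <- k + 1L
    gap <- if (k %in% contact_alleles) 100 else 5000
    base <- c(runif(1, -1e4, 1e4), runif(1, -1e4, 1e4), al * 4e4 + ci * 10)
    rows[[length(rows) + 1L]] <- data.table(
      cell_id = sprintf("c%02d", ci), se_id = loci$se_id, allele = al,
      x = base[1] + c(0, gap), y = base[2], z = base[3])
  }
  tab <- mk_table(rbindlist(rows), loci)
  pf <- pairwise_contact_frequency(tab, 200, "cis")
  expect_equal(pf$n_obs, 100L)
  expect_equal(pf$freq, 0.09)

  # never co-detected -> NA and flagged, not 0
  sp <- data.table::copy(tab$spots)
  sp[se_id == loci$se_id[2],
     `:=`(detected = FALSE, x = NA_real_, y = NA_real_, z = NA_real_)]
  pf2 <- pairwise_contact_frequency(cell_table(sp, loci), 200, "cis")
  expect_true(is.na(pf2$freq))
  expect_true(pf2$flagged)
})

test_that("trans scope uses any-allele per-cell contacts", {
  loci <- se_locus_table(data.table(
    chrom = c("chr1", "chr2"), start = c(0, 0), end = c(15000, 15000),
    name = c("A", "B")))
  tab <- mk_table(data.table(
    cell_id = "c1", se_id = rep(loci$se_id, each = 2), allele = rep(0:1, 2),
    x = c(0, 10000, 150, 20000), y = 0, z = 0), loci)
  pf <- pairwise_contact_frequency(tab, 200, "trans")
  # allele 0 of A is near allele 0 of B -> the cell counts once
  expect_equal(pf$n_contact, 1L)
  expect_equal(pf$n_obs, 1L)
})

test_that("threshold sweep is monotone and rank-stable on territories", {
  loci <- synthetic_locus_table(40, seed = 84)
  set.seed(84)
  tab <- simulate_territory_cells(loci, sim_config(n_cells = 40))
  sw <- threshold_sweep(tab, c(100, 400, 500, 600, 700))
  sizes <- sapply(sw$profiles, function(p)
    p$per_se$mean_cluster_size[order(p$per_se$se_id)])
  expect_true(all(apply(sizes, 1, function(v) all(diff(v) >= 0))))
  # 400 vs 700 nm per-SE sizes strongly correlated (cross-threshold
  # stability of the community ranking)
  expect_gt(sw$size_cor["400", "700"], 0.9)
  # radius below the minimum pairwise distance -> all sizes 1
  expect_true(all(sw$profiles[["100"]]$per_se$mean_cluster_size >= 1))
  tiny <- cluster_size_profile(mk_cell(cbind(c(0, 1e5), 0, 0), mk_loci(2)), 10)
  expect_true(all(tiny$per_se$mean_cluster_size == 1))
})

test_that("connected-component variant agrees on cliques and differs on chains", {
  loci <- mk_loci(3)
  # chain: A-B close, B-C close, A-C far
  chain <- mk_cell(cbind(c(0, 150, 300), 0, 0), loci)
  m <- pairwise_distance_map(chain)
  expect_equal(neighbor_counts(m, 200), c(1L, 2L, 1L))
  expect_equal(component_cluster_sizes(m, 200), c(3L, 3L, 3L))
})
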