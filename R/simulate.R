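# Synthetic-data generators: the uniform-random null used by the original
# analysis, a chromosome-territory generative model, detection dropout and
# localization noise, and a calibrated transcription-burst model. These
# stand in for the multi-terabyte imaging dataset so that every downstream
# stage is testable offline.

#' Simulation configuration
#'
#' Defaults state the conditions of the assay being emulated: a ~5 um-radius
#' mESC nucleus, 4,000 cells, 752 spots per cell (376 SEs x 2 alleles),
#' per-spot detection probability 0.9 and ~60 nm residual localization
#' error.
#'
#' @param nucleus_radius nucleus radius in nm (default 5000).
#' @param n_cells number of cells (default 4000).
#' @param n_points spots per cell for the null model (default 752).
#' @param detection_eff per-spot Bernoulli detection probability (default 0.9).
#' @param loc_noise_sigma target median 3D localization error in nm
#'   (default 60).
#' @param territory_spread per-axis jitter around the territory walk, nm
#'   (default 400).
#' @param persistence_scale random-walk step scale, nm per sqrt(Mb)
#'   (default 600).
#' @param n_attractors number of nuclear-landmark ("speckle") attractor
#'   points (default 8).
#' @param attractor_bias fraction of the distance to the nearest attractor
#'   that a high-affinity SE is displaced (default 0 = off).
#' @param burst_model a [burst_model()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(nucleus_radius = 5000, n_cells = 4000, n_points = 752,
                       detection_eff = 0.9, loc_noise_sigma = 60,
                       territory_spread = 400, persistence_scale = 600,
                       n_attractors = 8, attractor_bias = 0,
                       burst_model = secom::burst_model()) {
  stopifnot(nucleus_radius > 0, detection_eff >= 0, detection_eff <= 1,
            loc_noise_sigma >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic SE locus table
#'
#' A stand-in master list emulating the structure of the real SE catalog:
#' `n` standardized 15 kb targets spread over 19 autosomes plus chrX (2 SEs,
#' mirroring the sparse X), a dense histone-cluster-like block of 10 SEs
#' within 2 Mb, and ranked gene-linked SE families (`Nanog-0..3`,
#' `Sox2-0..1`, `Mycn-0..1`). A latent `affinity` column in \[0,1\] records
#' each SE's attraction to nuclear landmarks and drives the territory
#' simulation and the synthetic feature tracks. Synthetic: coordinates do
#' not correspond to any genome build.
#'
#' @param n number of loci (default 376).
#' @param seed optional seed applied locally (restores RNG state on exit).
#' @return `se_locus_table` with extra column `affinity`.
#' @export
synthetic_locus_table <- function(n = 376, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  chroms <- c(paste0("chr", 1:19), "chrX")
  # chrX deliberately sparse; chr13 hosts the dense histone-like block
  n_x <- min(2L, n)
  n_block <- if (n >= 60L) 10L else 0L
  n_rest <- n - n_x - n_block
  chrom <- c(rep("chrX", n_x), rep("chr13", n_block),
             sample(paste0("chr", 1:19), n_rest, replace = TRUE))
  center <- numeric(n)
  center[seq_len(n_x)] <- round(runif(n_x, 10e6, 150e6))
  if (n_block > 0)
    center[n_x + seq_len(n_block)] <- round(21e6 + sort(runif(n_block, 0, 2e6)))
  rest <- (n_x + n_block + 1):n
  center[rest] <- round(runif(length(rest), 5e6, 180e6))
  reg <- standardize_region(center)
  gene <- sprintf("Gene%03d", seq_len(n))
  gene[n_x + seq_len(n_block)] <- sprintf("Hist1h%02d", seq_len(n_block))
  # ranked SE families on fixed chromosomes
  fam <- list(Nanog = 4L, Sox2 = 2L, Mycn = 2L)
  i <- n_x + n_block
  for (g in names(fam)) {
    k <- fam[[g]]
    if (i + k > n) break
    idx <- i + seq_len(k)
    chrom[idx] <- c(Nanog = "chr6", Sox2 = "chr3", Mycn = "chr12")[g]
    base <- c(Nanog = 122e6, Sox2 = 34e6, Mycn = 12e6)[g]
    center[idx] <- round(base + cumsum(c(0, runif(k - 1, 5e4, 5e5))))
    reg[idx, ] <- standardize_region(center[idx])
    gene[idx] <- g
    i <- i + k
  }
  name <- gene
  for (g in names(fam)) {
    idx <- which(gene == g)
    name[idx] <- sprintf("%s-%d", g, seq_along(idx) - 1L)
  }
  loci <- data.table(se_id = sprintf("SE%03d", seq_len(n)), name = name,
                     chrom = chrom, start = reg[, "start"], end = reg[, "end"],
                     linked_gene = gene, dropped = FALSE)
  out <- se_locus_table(loci)
  # latent landmark affinity: high for the histone-like block and a random
  # third of the rest
  aff <- runif(n, 0, 0.3)
  aff[n_x + seq_len(n_block)] <- runif(n_block, 0.7, 1)
  hot <- sample(setdiff(seq_len(n), n_x + seq_len(n_block)), max(1L, n %/% 3))
  aff[hot] <- runif(length(hot), 0.5, 1)
  out[, affinity := aff]
  setorder(out, chrom, start)
  out[]
}

#' Sample points uniformly in a spherical nucleus
#'
#' Uses the exact inverse-CDF construction in spherical coordinates:
#' `theta = 2*pi*u`, `phi = acos(1 - 2*u)`, `r = R * u^(1/3)`, converted as
#' `x = r sin(phi) sin(theta)`, `y = r sin(phi) cos(theta)`,
#' `z = r cos(phi)`. The radial CDF is therefore `F(r) = (r/R)^3`.
#'
#' @param n_points number of points (>= 1).
#' @param radius sphere radius, nm.
#' @return matrix (n x 3) with columns x, y, z.
#' @export
sample_uniform_nucleus <- function(n_points, radius) {
  if (radius <= 0) stop("radius must be positive")
  stopifnot(n_points >= 1)
  theta <- 2 * pi * runif(n_points)
  phi <- acos(1 - 2 * runif(n_points))
  r <- radius * runif(n_points)^(1 / 3)
  cbind(x = r * sin(phi) * sin(theta),
        y = r * sin(phi) * cos(theta),
        z = r * cos(phi))
}

.spot_grid <- function(loci, n_cells) {
  n_loci <- nrow(loci)
  data.table(
    cell_id = rep(sprintf("cell%05d", seq_len(n_cells)), each = 2L * n_loci),
    fov_id = "fov0",
    se_id = rep(rep(loci$se_id, 2L), n_cells),
    allele = rep(rep(0:1, each = n_loci), n_cells))
}

#' Simulate the uniform-random null
#'
#' Every cell receives `n_points` spots placed independently and uniformly
#' in the spherical nucleus, labeled as the SE loci x 2 alleles. This is the
#' null model against which observed clustering is compared: at the default
#' geometry (752 points, 5 um radius, 200 nm contact radius) the expected
#' number of contact partners per spot is ~0.05, i.e. the average
#' contact-cluster size is ~1.
#'
#' @param config `sim_config`.
#' @param loci optional `se_locus_table` with `n_points / 2` rows; a
#'   synthetic one is generated when omitted.
#' @return `cell_table`.
#' @export
simulate_null_cells <- function(config = sim_config(), loci = NULL) {
  if (is.null(loci)) loci <- synthetic_locus_table(config$n_points %/% 2L)
  if (2L * nrow(loci) != config$n_points)
    stop("n_points must equal 2 x number of loci")
  sp <- .spot_grid(loci, config$n_cells)
  pts <- sample_uniform_nucleus(nrow(sp), config$nucleus_radius)
  sp[, `:=`(x = pts[, 1], y = pts[, 2], z = pts[, 3],
            detected = TRUE, quality = 1)]
  cell_table(sp, loci, meta = list(generator = "uniform_null",
                                   nucleus_radius = config$nucleus_radius))
}

#' Simulate chromosome-territory cells
#'
#' A generative model with the coarse features of real chromatin-tracing
#' data: each chromosome copy gets a territory center uniform in the
#' nucleus; SE positions follow a random walk along genomic order with
#' per-axis step scale `persistence_scale * sqrt(genomic step in Mb)` plus
#' `territory_spread` jitter; optionally, SEs are displaced toward the
#' nearest of `n_attractors` landmark points by
#' `attractor_bias * affinity`. Points falling outside the nucleus are
#' radially clipped to its surface.
#'
#' @param loci `se_locus_table` (an `affinity` column, if present, scales
#'   the attractor displacement per SE).
#' @param config `sim_config`.
#' @return `cell_table`.
#' @export
simulate_territory_cells <- function(loci, config = sim_config()) {
  R <- config$nucleus_radius
  lo <- as.data.table(loci)[dropped == FALSE]
  setorder(lo, chrom, start)
  aff <- if ("affinity" %in% names(lo)) lo$affinity else rep(0, nrow(lo))
  chrom_idx <- split(seq_len(nrow(lo)), lo$chrom)
  n_cells <- config$n_cells
  res <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    attractors <- sample_uniform_nucleus(max(config$n_attractors, 1L), R)
    pts <- matrix(NA_real_, 2L * nrow(lo), 3L)
    for (a in 0:1) {
      off <- a * nrow(lo)
      for (idx in chrom_idx) {
        ctr <- sample_uniform_nucleus(1L, R)
        mb <- lo$center[idx] / 1e6
        steps <- diff(mb)
        n_k <- length(idx)
        walk <- matrix(0, n_k, 3L)
        if (n_k > 1L) {
          inc <- matrix(rnorm(3L * (n_k - 1L)), n_k - 1L, 3L) *
            (config$persistence_scale * sqrt(pmax(steps, 1e-3)))
          walk[-1L, ] <- apply(inc, 2L, cumsum)
        }
        p <- sweep(walk, 2L, ctr[1, ], "+") +
          matrix(rnorm(3L * n_k, sd = config$territory_spread), n_k, 3L)
        if (config$attractor_bias > 0) {
          near <- .cross_dist(p, attractors)
          j <- max.col(-near)
          pull <- config$attractor_bias * aff[idx]
          p <- p + (attractors[j, , drop = FALSE] - p) * pull
        }
        nr <- sqrt(rowSums(p^2))
        out <- nr > R
        if (any(out)) p[out, ] <- p[out, , drop = FALSE] * (R / nr[out])
        pts[off + idx, ] <- p
      }
    }
    res[[ci]] <- pts
  }
  sp <- .spot_grid(lo, n_cells)
  pts <- do.call(rbind, res)
  sp[, `:=`(x = pts[, 1], y = pts[, 2], z = pts[, 3],
            detected = TRUE, quality = 1)]
  cell_table(sp, se_locus_table(lo), meta = list(generator = "territory",
                                                 nucleus_radius = R))
}

#' Apply detection dropout and localization noise
#'
#' Each spot is independently lost with probability `1 - eff`; retained
#' coordinates are perturbed by isotropic Gaussian noise with per-axis
#' standard deviation `sigma / sqrt(3)`, so that the median 3D displacement
#' is approximately `sigma` (the median of a chi(3) variate is ~1.538, and
#' 1.538 / sqrt(3) = 0.89).
#'
#' @param table `cell_table`.
#' @param eff detection probability in \[0,1\].
#' @param sigma target 3D localization error scale, nm.
#' @return new `cell_table`.
#' @export
apply_detection_noise <- function(table, eff = 0.9, sigma = 60) {
  stopifnot(eff >= 0, eff <= 1, sigma >= 0)
  sp <- copy(table$spots)
  if (eff < 1) {
    keep <- runif(nrow(sp)) < eff
    sp[!keep, `:=`(detected = FALSE, x = NA_real_, y = NA_real_, z = NA_real_)]
  }
  if (sigma > 0) {
    det <- which(sp$detected)
    noise <- matrix(rnorm(3L * length(det), sd = sigma / sqrt(3)),
                    length(det), 3L)
    sp[det, `:=`(x = x + noise[, 1], y = y + noise[, 2], z = z + noise[, 3])]
  }
  meta <- table$meta
  meta$detection_eff <- eff
  meta$loc_noise_sigma <- sigma
  cell_table(sp, table$loci, meta)
}

# ---- Burst model -----------------------------------------------------------

#' Transcription-burst model
#'
#' Generative stand-in for the community-size dependence of nascent
#' transcription: an allele whose promoter-linked SE sits in a community of
#' size `s` bursts with probability
#' `p(s) = plogis(qlogis(baseline_p) + delta(s))`, where `delta` is a
#' per-size log-odds offset anchored at stated sizes (linear interpolation
#' in between, constant beyond). With the default anchors the expected odds
#' ratios versus isolated alleles are exp(0.2231) = 1.25 at size 3 and
#' exp(1.0986) = 3 at size 10. Burst intensity is log-normal, multiplied by
#' `coburst_gain` per active neighboring gene within the community radius;
#' silent alleles have intensity 0.
#'
#' @param baseline_p burst probability of an isolated allele (default 0.2).
#' @param logodds_anchors named numeric vector: community size -> log-odds
#'   offset; must include size 1 with offset 0.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity parameters
#'   (arbitrary units).
#' @param coburst_gain multiplicative intensity factor per active neighbor
#'   (default 1.3).
#' @return list of class `burst_model`.
#' @export
burst_model <- function(baseline_p = 0.2,
                        logodds_anchors = c("1" = 0, "3" = 0.2231, "10" = 1.0986),
                        intensity_meanlog = log(100), intensity_sdlog = 0.5,
                        coburst_gain = 1.3) {
  stopifnot(baseline_p >= 0, baseline_p <= 1)
  s <- as.numeric(names(logodds_anchors))
  if (!1 %in% s || logodds_anchors[which(s == 1)] != 0)
    stop("logodds_anchors must anchor delta(1) = 0")
  o <- order(s)
  structure(list(baseline_p = baseline_p, anchor_s = s[o],
                 anchor_delta = unname(logodds_anchors[o]),
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 coburst_gain = coburst_gain), class = "burst_model")
}

#' Log-odds offset delta(s) of a burst model
#' @param model `burst_model`.
#' @param s community sizes.
#' @export
burst_logodds_offset <- function(model, s) {
  if (length(model$anchor_s) == 1L) return(rep(model$anchor_delta, length(s)))
  stats::approx(model$anchor_s, model$anchor_delta, xout = s, rule = 2)$y
}

#' Burst probability p(s)
#' @rdname burst_logodds_offset
#' @export
burst_probability <- function(model, s) {
  plogis(qlogis(model$baseline_p) + burst_logodds_offset(model, s))
}

#' Draw burst states for alleles of given community sizes
#'
#' The direct calibration generator: alleles with community sizes `sizes`
#' burst independently with probability `p(s)` from the model. Used to
#' verify that downstream odds-ratio estimation recovers the generative
#' per-size odds.
#'
#' @param sizes integer vector of community sizes (one per allele).
#' @param model `burst_model`.
#' @return data.table with columns `size`, `on`.
#' @export
simulate_size_bursts <- function(sizes, model = burst_model()) {
  p <- burst_probability(model, sizes)
  data.table(size = sizes, on = runif(length(sizes)) < p)
}

#' Attach nascent-transcription bursts to a simulated cell table
#'
#' For each (cell, gene, allele), the community size of the gene's
#' promoter-linked SE spot is computed (spots within `community_radius`),
#' the allele bursts with probability `p(s)`, and bursting alleles draw a
#' log-normal intensity scaled by `coburst_gain` per other bursting
#' gene-linked SE within the community radius in the same cell.
#'
#' @param table `cell_table`.
#' @param genes data.frame with columns `gene`, `se_id` (promoter-linked SE
#'   per assayed gene).
#' @param model `burst_model`.
#' @param community_radius nm, default 600.
#' @return data.table of burst records: `cell_id`, `gene`, `se_id`,
#'   `allele`, `community_size`, `on`, `intensity`.
#' @export
attach_bursts <- function(table, genes, model = burst_model(),
                          community_radius = 600) {
  genes <- as.data.table(genes)
  missing_se <- setdiff(genes$se_id, table$loci$se_id)
  if (length(missing_se))
    stop("gene-linked se_id absent from locus table: ",
         paste(missing_se, collapse = ", "))
  sp <- table$spots
  recs <- vector("list", length(unique(sp$cell_id)))
  k <- 0L
  for (cid in unique(sp$cell_id)) {
    cs <- sp[cell_id == cid]
    dm <- .spot_dist(cs)
    cnt <- neighbor_counts_matrix(dm, community_radius)
    idx <- which(cs$se_id %in% genes$se_id)
    if (!length(idx)) next
    g <- genes[match(cs$se_id[idx], genes$se_id)]
    size <- 1L + cnt[idx]
    p <- burst_probability(model, size)
    p[!cs$detected[idx]] <- NA
    on <- runif(length(idx)) < p
    on[is.na(on)] <- FALSE
    # active gene-linked neighbors within the community radius
    pos_active <- idx[on]
    n_active_nb <- vapply(seq_along(idx), function(i) {
      if (!on[i]) return(0L)
      d <- dm[idx[i], pos_active]
      sum(d < community_radius & pos_active != idx[i], na.rm = TRUE)
    }, integer(1))
    intensity <- numeric(length(idx))
    nb <- sum(on)
    if (nb > 0)
      intensity[on] <- rlnorm(nb, model$intensity_meanlog,
                              model$intensity_sdlog) *
        model$coburst_gain^n_active_nb[on]
    k <- k + 1L
    recs[[k]] <- data.table(cell_id = cid, gene = g$gene,
                            se_id = cs$se_id[idx], allele = cs$allele[idx],
                            community_size = size, on = on,
                            intensity = intensity)
  }
  rbindlist(recs[seq_len(k)])
}

#' Synthetic per-SE feature tracks
#'
#' Generates per-SE predictor signals (Pol2, Med1, Oct4/Sox2/Nanog, K27ac,
#' LAD score, speckle score) as linear loadings on the generative drivers of
#' community size -- genomic tether density (from [tether_metrics()]) and
#' landmark affinity -- plus Gaussian noise, and optionally writes matching
#' bedGraph text fixtures. Positive `pol2`/`med1`/`speckle` loadings and a
#' negative `lad` loading mirror the directions the assay reports.
#'
#' @param loci `se_locus_table` (uses `affinity` when present).
#' @param noise_sd feature noise standard deviation (features are generated
#'   on a unit scale), default 0.3.
#' @param loadings named list with elements `tether` and `affinity`, each a
#'   named numeric vector of loadings per feature.
#' @param bedgraph_dir if non-NULL, write one bedGraph file per feature.
#' @return `data.table` (one row per non-dropped SE) with feature columns
#'   plus `n_se_1mb`, `inv_dist_sum`, `chrom`.
#' @export
synth_feature_tracks <- function(loci, noise_sd = 0.3,
                                 loadings = NULL, bedgraph_dir = NULL) {
  lo <- as.data.table(loci)[dropped == FALSE]
  aff <- if ("affinity" %in% names(lo)) lo$affinity else rep(0, nrow(lo))
  tm <- tether_metrics(lo)
  tether <- as.numeric(scale(tm$n_se_1mb + tm$inv_dist_sum))
  affz <- as.numeric(scale(aff))
  if (is.null(loadings))
    loadings <- list(
      tether = c(pol2 = 0.3, med1 = 0.25, oct4 = -0.1, sox2 = -0.1,
                 nanog = -0.1, k27ac = 0, lad_score = 0, speckle_score = 0.2),
      affinity = c(pol2 = 0.3, med1 = 0.3, oct4 = -0.15, sox2 = -0.15,
                   nanog = -0.15, k27ac = 0, lad_score = -0.8,
                   speckle_score = 0.8))
  feats <- names(loadings$tether)
  ft <- data.table(se_id = lo$se_id)
  for (f in feats) {
    set(ft, j = f, value = loadings$tether[[f]] * tether +
          loadings$affinity[[f]] * affz + rnorm(nrow(lo), sd = noise_sd))
  }
  ft[, `:=`(n_se_1mb = tm$n_se_1mb, inv_dist_sum = tm$inv_dist_sum,
            chrom = lo$chrom)]
  if (!is.null(bedgraph_dir)) {
    dir.create(bedgraph_dir, showWarnings = FALSE, recursive = TRUE)
    for (f in feats) {
      bg <- data.table(chrom = lo$chrom, start = as.integer(lo$start),
                       end = as.integer(lo$end),
                       value = round(ft[[f]] - min(ft[[f]]) + 0.01, 4))
      setorder(bg, chrom, start)
      fwrite(bg, file.path(bedgraph_dir, paste0(f, ".bedgraph")),
             sep = "\t", col.names = FALSE)
    }
  }
  ft[]
}
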