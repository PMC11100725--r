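# Per-cell distance maps, contact (200 nm) and community (600 nm) calling,
# and per-SE cluster-size statistics. Cluster/community size is the
# star/neighborhood count: 1 + number of other spots within the radius
# (strictly <; ties at exactly the radius are excluded). A transitive
# connected-component variant is available behind a flag for sensitivity
# analysis.

# Distance matrix over the spots of one cell (rows of a spot data.table);
# NA rows/columns for undetected spots.
.spot_dist <- function(cs) {
  p <- as.matrix(cs[, c("x", "y", "z")])
  d <- as.matrix(dist(p))
  nd <- !cs$detected
  if (any(nd)) { d[nd, ] <- NA_real_; d[, nd] <- NA_real_ }
  dimnames(d) <- list(paste0(cs$se_id, "@", cs$allele),
                      paste0(cs$se_id, "@", cs$allele))
  d
}

#' Per-cell all-vs-all distance map
#'
#' Euclidean distances between every pair of spots of one cell; entries
#' involving an undetected spot are `NA` (missingness is propagated, never
#' imputed).
#'
#' @param cell `cell_table`.
#' @param cell_id cell to extract (defaults to the only/first cell).
#' @return object of class `distance_map`: `d` (symmetric matrix, nm),
#'   `se_id`, `allele`, `detected`, `cell_id`.
#' @export
pairwise_distance_map <- function(cell, cell_id = NULL) {
  sp <- cell$spots
  if (is.null(cell_id)) cell_id <- sp$cell_id[1]
  sel <- which(sp$cell_id == cell_id)  # plain-R eval, outside `[`
  cs <- sp[sel]
  if (sum(cs$detected) < 2L) stop("need >= 2 detected spots in cell ", cell_id)
  structure(list(cell_id = cell_id, d = .spot_dist(cs), se_id = cs$se_id,
                 allele = cs$allele, detected = cs$detected),
            class = "distance_map")
}

# counts of other spots strictly within radius, per spot row; NA spots give NA
neighbor_counts_matrix <- function(d, radius) {
  cnt <- rowSums(d < radius, na.rm = TRUE)
  det <- !is.na(diag(d))
  cnt[det] <- cnt[det] - 1L  # remove self (diagonal is 0)
  cnt[!det] <- NA_integer_
  as.integer(cnt)
}

#' Neighbor counts at a radius
#'
#' For each detected spot, the number of other detected spots at distance
#' strictly less than `radius`; pairs with a missing endpoint contribute
#' nothing, and undetected spots get `NA`.
#'
#' @param map `distance_map`.
#' @param radius nm, > 0.
#' @return integer vector, one entry per spot.
#' @export
neighbor_counts <- function(map, radius) {
  stopifnot(radius > 0)
  neighbor_counts_matrix(map$d, radius)
}

# long table of (cell_id, se_id, allele, count) over all cells
.all_neighbor_counts <- function(table, radius) {
  sp <- table$spots
  sp[, {
    cnt <- if (sum(detected) >= 1L)
      neighbor_counts_matrix(.spot_dist(.SD), radius)
    else rep(NA_integer_, .N)
    list(se_id = se_id, allele = allele, count = cnt)
  }, by = cell_id]
}

#' Per-SE cluster-size profile at one radius
#'
#' Computes, per SE: the distribution of partner counts (0, 1, 2, 3, 4+
#' other SEs within the radius) across detected spots, the mean cluster
#' size, and the 95th-percentile largest cluster across all cells. To
#' correct for missed detections, the mean partner count is divided by the
#' mean per-spot detection frequency of the potential partners before
#' adding 1:
#' `mean_cluster_size = 1 + raw_mean_partners / partner_detection`.
#' A per-cell mean cluster size (average of `1 + count` over the cell's
#' detected spots) is also returned.
#'
#' @param table `cell_table`.
#' @param radius nm (200 for contacts, 600 for communities).
#' @param detect_stats result of [detection_efficiency()]; when `NULL`,
#'   detection is assumed perfect and raw and normalized profiles coincide.
#' @return object of class `cluster_profile` with `per_se`, `per_cell`,
#'   `radius`, `detection_normalized`.
#' @export
cluster_size_profile <- function(table, radius, detect_stats = NULL) {
  stopifnot(radius > 0)
  long <- .all_neighbor_counts(table, radius)
  long <- long[!is.na(count)]
  per_se <- long[, .(
    freq0 = mean(count == 0L), freq1 = mean(count == 1L),
    freq2 = mean(count == 2L), freq3 = mean(count == 3L),
    freq4plus = mean(count >= 4L),
    raw_mean_partners = mean(count),
    p95_cluster_size = as.numeric(quantile(1L + count, 0.95)),
    n_obs = .N), by = se_id]
  if (!is.null(detect_stats)) {
    eff <- detect_stats$per_se
    zero <- eff$se_id[eff$spot_freq == 0]
    if (length(zero)) {
      warning("excluding SE(s) with zero detection frequency: ",
              paste(zero, collapse = ", "))
      per_se <- per_se[!se_id %in% zero]
      eff <- eff[!se_id %in% zero]
    }
    partner_eff <- vapply(per_se$se_id, function(s)
      mean(eff$spot_freq[eff$se_id != s]), numeric(1))
    per_se[, mean_cluster_size := 1 + raw_mean_partners / partner_eff]
  } else {
    per_se[, mean_cluster_size := 1 + raw_mean_partners]
  }
  per_cell <- long[, .(mean_cluster_size = mean(1L + count)), by = cell_id]
  # allele-level rows (both alleles of an SE share genomic features but are
  # measured independently)
  per_allele <- long[, .(raw_mean_partners = mean(count), n_obs = .N),
                     by = .(se_id, allele)]
  pe <- per_se[match(per_allele$se_id, se_id)]
  per_allele[, mean_cluster_size :=
               1 + raw_mean_partners * (pe$mean_cluster_size - 1) /
               pmax(pe$raw_mean_partners, .Machine$double.eps)]
  setorder(per_allele, se_id, allele)
  structure(list(radius = radius, per_se = per_se[],
                 per_allele = per_allele[], per_cell = per_cell[],
                 detection_normalized = !is.null(detect_stats)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> radius %g nm, %d SEs; mean cluster size %.3f (normalized: %s)\n",
              x$radius, nrow(x$per_se), mean(x$per_se$mean_cluster_size),
              x$detection_normalized))
  invisible(x)
}

#' Connected-component cluster sizes (sensitivity variant)
#'
#' Alternative cluster definition: sizes of the transitive connected
#' components of the within-radius proximity graph of one cell. Provided
#' for sensitivity analysis only; the primary statistics use the
#' star/neighborhood count.
#'
#' @param map `distance_map`.
#' @param radius nm.
#' @return integer vector: component size per spot (NA for undetected).
#' @export
component_cluster_sizes <- function(map, radius) {
  d <- map$d
  n <- nrow(d)
  adj <- !is.na(d) & d < radius
  comp <- rep(NA_integer_, n)
  det <- which(is.finite(diag(d)))
  nxt <- 0L
  for (v in det) {
    if (!is.na(comp[v])) next
    nxt <- nxt + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- nxt
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  sz <- table(comp)
  out <- rep(NA_integer_, n)
  out[!is.na(comp)] <- as.integer(sz[as.character(comp[!is.na(comp)])])
  out
}

#' Pairwise SE-SE contact frequency
#'
#' For `scope = "cis"` (pairs on the same chromosome) the frequency is per
#' allele: both endpoints must be detected in the same allele group, and
#' the pair counts when their distance is below `radius`. For `"trans"` or
#' `"all"`, the frequency is per cell with any-allele combination allowed.
#' Pairs never co-detected get `freq = NA` and are flagged rather than
#' reported as 0.
#'
#' @param table `cell_table`.
#' @param radius nm, default 200.
#' @param scope `"cis"`, `"trans"` or `"all"`.
#' @return data.table: `se_a`, `se_b`, `n_contact`, `n_obs`, `freq`,
#'   `flagged`.
#' @export
pairwise_contact_frequency <- function(table, radius = 200,
                                       scope = c("cis", "trans", "all")) {
  scope <- match.arg(scope)
  loci <- table$loci
  chrom <- setNames(loci$chrom, loci$se_id)
  ids <- loci$se_id
  np <- length(ids)
  n_contact <- n_obs <- matrix(0L, np, np, dimnames = list(ids, ids))
  sp <- table$spots
  for (cid in unique(sp$cell_id)) {
    cs <- sp[cell_id == cid]
    d <- .spot_dist(cs)
    if (scope == "cis") {
      for (a in unique(cs$allele)) {
        ai <- which(cs$allele == a & cs$detected)
        if (length(ai) < 2L) next
        sub <- d[ai, ai, drop = FALSE]
        sid <- cs$se_id[ai]
        ii <- match(sid, ids)
        n_obs[ii, ii] <- n_obs[ii, ii] + 1L
        n_contact[ii, ii] <- n_contact[ii, ii] + (sub < radius)
      }
    } else {
      det <- cs[detected == TRUE]
      pres <- unique(det$se_id)
      ii <- match(pres, ids)
      n_obs[ii, ii] <- n_obs[ii, ii] + 1L
      # any spot-pair proximity between the two SEs
      hit <- matrix(FALSE, length(pres), length(pres))
      di <- which(cs$detected)
      sub <- d[di, di, drop = FALSE] < radius
      sid <- match(cs$se_id[di], pres)
      for (k in seq_along(di)) {
        hits <- unique(sid[sub[k, ]])
        hit[sid[k], hits] <- TRUE
      }
      n_contact[ii, ii] <- n_contact[ii, ii] + hit
    }
  }
  pairs <- CJ(a = seq_len(np), b = seq_len(np))[a < b]
  out <- data.table(se_a = ids[pairs$a], se_b = ids[pairs$b],
                    n_contact = n_contact[cbind(pairs$a, pairs$b)],
                    n_obs = n_obs[cbind(pairs$a, pairs$b)])
  same_chrom <- chrom[out$se_a] == chrom[out$se_b]
  if (scope == "cis") out <- out[same_chrom]
  if (scope == "trans") out <- out[!same_chrom]
  out[, freq := ifelse(n_obs > 0, n_contact / n_obs, NA_real_)]
  out[, flagged := n_obs == 0L]
  out[]
}

#' Cluster-size profiles across a sweep of radii
#'
#' Profiles at each radius (ascending), plus the Pearson correlation matrix
#' of per-SE mean cluster sizes across radii -- the cross-threshold
#' stability check (neighboring thresholds in the 400-700 nm range should
#' correlate strongly on territory-structured data).
#'
#' @param table `cell_table`.
#' @param radii numeric vector of radii, nm, sorted ascending.
#' @param detect_stats optional [detection_efficiency()] result.
#' @return list: `profiles` (named by radius), `size_cor` (Pearson r matrix
#'   of per-SE mean sizes).
#' @export
threshold_sweep <- function(table, radii, detect_stats = NULL) {
  if (is.unsorted(radii)) stop("radii must be sorted ascending")
  profiles <- lapply(radii, function(r)
    cluster_size_profile(table, r, detect_stats))
  names(profiles) <- as.character(radii)
  sizes <- vapply(profiles, function(p)
    p$per_se$mean_cluster_size[order(p$per_se$se_id)],
    numeric(nrow(profiles[[1]]$per_se)))
  list(profiles = profiles, size_cor = cor(sizes))
}
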