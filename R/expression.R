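# Couple nascent-transcription bursts to SE community geometry: punctum
# association, intensity-vs-community-size coupling, per-size odds ratios,
# conditional distance maps, and co-bursting statistics.

#' Associate nascent-RNA puncta with gene-linked SE alleles
#'
#' Each (cell, gene, allele) is scored by the amplitude of the nearest RNA
#' punctum within `search_radius` of the promoter-linked SE spot of that
#' allele; alleles with no punctum in range (or an undetected SE spot) get
#' intensity 0. A punctum is assigned to at most one allele (globally
#' nearest first); exact distance ties go to the lexicographically first
#' (cell, gene, allele) and are logged.
#'
#' @param table `cell_table`.
#' @param puncta data.frame: `cell_id`, `x`, `y`, `z` (nm), `amplitude`.
#' @param genes data.frame: `gene`, `se_id` (promoter-linked SE).
#' @param search_radius nm, default 1000.
#' @return data.table of burst records: `cell_id`, `gene`, `se_id`,
#'   `allele`, `intensity`, `on`.
#' @export
associate_bursts <- function(table, puncta, genes, search_radius = 1000) {
  puncta <- as.data.table(puncta)
  genes <- as.data.table(genes)
  missing_se <- setdiff(genes$se_id, table$loci$se_id)
  if (length(missing_se))
    stop("gene-linked se_id absent from locus table: ",
         paste(missing_se, collapse = ", "))
  alle <- table$spots[se_id %in% genes$se_id]
  alle <- merge(alle, genes, by = "se_id")
  alle[, intensity := 0]
  setorder(alle, cell_id, gene, allele)
  for (cid in unique(alle$cell_id)) {
    pu <- puncta[cell_id == cid]
    ai <- which(alle$cell_id == cid & alle$detected)
    if (!nrow(pu) || !length(ai)) next
    d <- .cross_dist(as.matrix(alle[ai, .(x, y, z)]),
                     as.matrix(pu[, .(x, y, z)]))
    cand <- which(d <= search_radius, arr.ind = TRUE)
    if (!nrow(cand)) next
    dd <- d[cand]
    if (anyDuplicated(dd[order(dd)]) && length(unique(dd)) < length(dd))
      message("punctum distance tie in cell ", cid,
              ": assigned to first allele in (cell, gene, allele) order")
    # greedy nearest-first; row order of `alle` breaks exact ties
    ord <- order(dd, cand[, 1L])
    used_a <- logical(length(ai)); used_p <- logical(nrow(pu))
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (used_a[i] || used_p[j]) next
      used_a[i] <- used_p[j] <- TRUE
      alle[ai[i], intensity := pu$amplitude[j]]
    }
  }
  out <- alle[, .(cell_id, gene, se_id, allele, intensity, on = intensity > 0)]
  out[]
}

#' Burst intensity versus community size
#'
#' Pearson correlation of nascent-transcript intensity with the community
#' size of the promoter-linked SE, across alleles, plus per-size intensity
#' summaries and allele counts per size.
#'
#' @param records burst records carrying a `community_size` column (e.g.
#'   from [attach_bursts()]), or supply `sizes` alongside.
#' @param sizes optional integer vector aligned with `records` rows.
#' @return list: `r`, `p_value`, `n`, `per_size` (data.table of median/mean
#'   intensity, burst fraction and allele count per size).
#' @export
burst_vs_community <- function(records, sizes = NULL) {
  rec <- as.data.table(records)
  if (!is.null(sizes)) rec[, community_size := sizes]
  if (!"community_size" %in% names(rec) && "size" %in% names(rec))
    setnames(rec, "size", "community_size")
  if (!"community_size" %in% names(rec))
    stop("records lack community_size; supply `sizes`")
  if (nrow(rec) < 3L) stop("need at least 3 records")
  per_size <- rec[, .(n_alleles = .N, burst_frac = mean(on),
                      mean_intensity = mean(intensity),
                      median_intensity = median(intensity)),
                  by = .(size = community_size)][order(size)]
  if (sd(rec$intensity) == 0 || sd(rec$community_size) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(rec),
                per_size = per_size[], flagged = TRUE))
  }
  ct <- cor.test(rec$intensity, rec$community_size)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(rec),
       per_size = per_size[], flagged = FALSE)
}

#' Odds ratio of bursting by community size
#'
#' For each community size `s`, the odds ratio of active transcription
#' versus the isolated baseline (`size == baseline_size`): exposure = the
#' allele's SE sits in a community of size `s`, condition = the allele is
#' bursting.
#'
#' @param records burst records with `on` and `community_size` (or supply
#'   `sizes`).
#' @param sizes optional integer vector aligned with rows.
#' @param baseline_size baseline bin, default 1 (isolated).
#' @param correction passed to [odds_ratio()].
#' @return data.table: `size`, counts `a`,`b`,`c`,`d`, `or`, `flagged`.
#' @export
bursting_odds_by_size <- function(records, sizes = NULL, baseline_size = 1L,
                                  correction = "none") {
  rec <- as.data.table(records)
  if (!is.null(sizes)) rec[, community_size := sizes]
  if (!"community_size" %in% names(rec) && "size" %in% names(rec))
    setnames(rec, "size", "community_size")
  if (!"community_size" %in% names(rec))
    stop("records lack community_size; supply `sizes`")
  base <- rec[community_size == baseline_size]
  if (!nrow(base)) stop("no records at baseline size ", baseline_size)
  cc <- sum(base$on); dd <- sum(!base$on)
  out <- rec[community_size != baseline_size,
             .(a = sum(on), b = sum(!on)), by = .(size = community_size)]
  setorder(out, size)
  ors <- lapply(seq_len(nrow(out)), function(i)
    odds_ratio(out$a[i], out$b[i], cc, dd, correction = correction))
  out[, `:=`(c = cc, d = dd,
             or = vapply(ors, `[[`, numeric(1), "or"),
             flagged = vapply(ors, `[[`, logical(1), "flagged"))]
  out[]
}

# median per-pair distance map over a set of (cell, allele) groups
.median_pair_map <- function(table, alleles_dt) {
  ids <- table$loci$se_id
  n <- length(ids)
  acc <- vector("list", nrow(alleles_dt))
  sp <- table$spots
  for (k in seq_len(nrow(alleles_dt))) {
    cs <- sp[cell_id == alleles_dt$cell_id[k] & allele == alleles_dt$allele[k]]
    d <- .spot_dist(cs)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    ii <- match(cs$se_id, ids)
    m[ii, ii] <- d
    acc[[k]] <- m
  }
  arr <- simplify2array(acc)
  apply(arr, c(1, 2), median, na.rm = TRUE)
}

#' Median distance maps conditioned on burst state
#'
#' Per-pair median SE-SE distances computed separately over transcriptionally
#' on and off alleles of one gene, and their difference (off - on). A
#' predominantly positive difference means the bursting population sits in
#' globally tighter SE configurations.
#'
#' @param table `cell_table`.
#' @param records burst records for (at least) `gene`.
#' @param gene gene symbol.
#' @param min_alleles minimum alleles required in each state, default 20.
#' @return list: `on`, `off` (median maps, nm), `diff` (off - on),
#'   `frac_positive` (fraction of finite pairs with positive difference),
#'   `n_on`, `n_off`.
#' @export
conditional_distance_maps <- function(table, records, gene, min_alleles = 20L) {
  rec <- as.data.table(records)
  sel <- which(rec$gene == gene)
  rec <- rec[sel]
  on_set <- rec[on == TRUE, .(cell_id, allele)]
  off_set <- rec[on == FALSE, .(cell_id, allele)]
  if (nrow(on_set) < min_alleles || nrow(off_set) < min_alleles)
    stop("need >= ", min_alleles, " alleles in each burst state (on: ",
         nrow(on_set), ", off: ", nrow(off_set), ")")
  m_on <- .median_pair_map(table, on_set)
  m_off <- .median_pair_map(table, off_set)
  dmap <- m_off - m_on
  ut <- upper.tri(dmap) & is.finite(dmap)
  list(on = m_on, off = m_off, diff = dmap,
       frac_positive = mean(dmap[ut] > 0),
       n_on = nrow(on_set), n_off = nrow(off_set))
}

#' Co-bursting statistics
#'
#' For every bursting allele, the number of other bursting gene-linked SEs
#' within `radius` in the same cell; the Pearson correlation of burst
#' intensity with that count; and, over a grid of burst-size thresholds
#' `theta`, the odds ratio of "burst size exceeds theta" given "at least
#' one other bursting SE within the radius" (a co-burst community of more
#' than one).
#'
#' @param records burst records (>= 2 distinct genes required).
#' @param table `cell_table` the records refer to.
#' @param radius nm, default 600.
#' @param theta_grid thresholds; default: deciles of the positive
#'   intensities.
#' @param correction passed to [odds_ratio()].
#' @return list: `active` (records with `n_active_nb`), `r`, `p_value`,
#'   `or_curve` (data.table theta, a, b, c, d, or, flagged).
#' @export
coburst_statistics <- function(records, table, radius = 600,
                               theta_grid = NULL, correction = "none") {
  rec <- as.data.table(records)
  if (length(unique(rec$gene)) < 2L)
    stop("co-bursting undefined with a single assayed gene")
  act <- rec[on == TRUE]
  pos <- merge(act, table$spots[, .(cell_id, se_id, allele, x, y, z, detected)],
               by = c("cell_id", "se_id", "allele"))
  pos <- pos[detected == TRUE]
  pos[, n_active_nb := 0L]
  for (cid in unique(pos$cell_id)) {
    idx <- which(pos$cell_id == cid)
    if (length(idx) < 2L) next
    d <- .cross_dist(as.matrix(pos[idx, .(x, y, z)]),
                     as.matrix(pos[idx, .(x, y, z)]))
    diag(d) <- Inf
    pos[idx, n_active_nb := as.integer(rowSums(d < radius))]
  }
  r <- NA_real_; pv <- NA_real_
  if (nrow(pos) >= 3L && sd(pos$intensity) > 0 && sd(pos$n_active_nb) > 0) {
    ct <- cor.test(pos$intensity, pos$n_active_nb)
    r <- unname(ct$estimate); pv <- ct$p.value
  }
  if (is.null(theta_grid))
    theta_grid <- unique(quantile(pos$intensity[pos$intensity > 0],
                                  probs = seq(0.1, 0.9, by = 0.1)))
  exposed <- pos$n_active_nb >= 1L
  curve <- rbindlist(lapply(theta_grid, function(th) {
    cond <- pos$intensity > th
    o <- odds_ratio(sum(exposed & cond), sum(exposed & !cond),
                    sum(!exposed & cond), sum(!exposed & !cond),
                    correction = correction)
    data.table(theta = th, a = sum(exposed & cond), b = sum(exposed & !cond),
               c = sum(!exposed & cond), d = sum(!exposed & !cond),
               or = o$or, flagged = o$flagged)
  }))
  list(active = pos[], r = r, p_value = pv, or_curve = curve[])
}
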