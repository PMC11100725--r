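library(data.table)

# build a small locus table from bare coordinates
mk_loci <- function(n, chrom = "chr1", spacing = 1e6, start0 = 10e6) {
  centers <- start0 + (seq_len(n) - 1L) * spacing
  reg <- standardize_region(centers)
  se_locus_table(data.table(
    chrom = rep(chrom, length.out = n),
    start = reg[, "start"], end = reg[, "end"],
    name = sprintf("SE%02d", seq_len(n))))
}

# build a one-or-more-cell table from an explicit coordinate table:
# coords = data.table(cell_id, se_id, allele, x, y, z[, detected])
mk_table <- function(coords, loci) {
  co <- as.data.table(coords)
  if (!"detected" %in% names(co)) co[, detected := TRUE]
  cell_table(co, loci)
}

# single-cell table with one spot (allele 0) per locus at given positions
mk_cell <- function(pts, loci, cell = "c1") {
  pts <- as.matrix(pts)
  mk_table(data.table(cell_id = cell, se_id = loci$se_id[seq_len(nrow(pts))],
                      allele = 0L, x = pts[, 1], y = pts[, 2], z = pts[, 3]),
           loci)
}

# --- independent oracles -----------------------------------------------------

# neighbor counts by explicit double loop (strict <)
brute_neighbor_counts <- function(pts, detected, radius) {
  n <- nrow(pts)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!detected[i]) next
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i || !detected[j]) next
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < radius) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

# exhaustive minimum of the allele-assignment objective over all valid
# partitions (two-spot SEs split across groups; singles free)
brute_allele_optimum <- function(pts, se_of_spot) {
  ses <- split(seq_along(se_of_spot), se_of_spot)
  n_se <- length(ses)
  best <- Inf
  for (code in 0:(2^n_se - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(n_se)]
    grp <- integer(length(se_of_spot))
    for (k in seq_len(n_se)) {
      idx <- ses[[k]]
      if (length(idx) == 2L) {
        grp[idx[1]] <- bits[k]; grp[idx[2]] <- 1L - bits[k]
      } else grp[idx] <- bits[k]
    }
    obj <- 0
    for (g in 0:1) {
      m <- pts[grp == g, , drop = FALSE]
      if (nrow(m) > 1L) obj <- obj + sum(dist(m))
    }
    best <- min(best, obj)
  }
  best
}

# independent Bernoulli proximity events (no geometry): detection with
# probability p_det, each unordered pair proximate with probability p_pair
random_events <- function(n_se, n_cells, p_pair, p_det = 1) {
  ids <- sprintf("E%02d", seq_len(n_se))
  det <- matrix(runif(n_cells * n_se) < p_det, n_cells, n_se,
                dimnames = list(NULL, ids))
  adj <- array(FALSE, c(n_se, n_se, n_cells), dimnames = list(ids, ids, NULL))
  for (k in seq_len(n_cells)) {
    for (u in seq_len(n_se - 1L)) for (v in (u + 1L):n_se) {
      if (runif(1) < p_pair) adj[u, v, k] <- adj[v, u, k] <- TRUE
    }
  }
  as_proximity_events(det, adj)
}
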