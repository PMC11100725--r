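# Point-level corrections applied before any distance analysis:
# chromatic-aberration warp fitting, allele assignment, detection-efficiency
# and replicate-error quantification.

#' Match points between two channels by unambiguous mutual proximity
#'
#' Pairs spots imaged in two chromatic channels. A point is retained only if
#' it has exactly one counterpart within `max_dist` and that counterpart
#' likewise has exactly one candidate: points with zero or multiple
#' candidates within the radius are rejected outright (ambiguity is never
#' resolved by distance), so every retained point has a unique matched pair.
#'
#' @param set_a,set_b numeric matrices (n x 3), nm coordinates in a common
#'   frame.
#' @param max_dist matching radius in nm (default 1000).
#' @return list with `a`, `b` (matched rows, same order), `dist` (pair
#'   distances) and `rejected` (count of unmatched/ambiguous points).
#' @export
match_point_pairs <- function(set_a, set_b, max_dist = 1000) {
  set_a <- as.matrix(set_a); set_b <- as.matrix(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L)
    return(list(a = set_a[0, , drop = FALSE], b = set_b[0, , drop = FALSE],
                dist = numeric(), rejected = nrow(set_a) + nrow(set_b)))
  d <- .cross_dist(set_a, set_b)
  within <- d <= max_dist
  cand_a <- rowSums(within)   # candidates in b for each a
  cand_b <- colSums(within)   # candidates in a for each b
  ia <- which(cand_a == 1L)
  jb <- apply(within[ia, , drop = FALSE], 1L, which.max)
  keep <- cand_b[jb] == 1L
  ia <- ia[keep]; jb <- jb[keep]
  list(a = set_a[ia, , drop = FALSE], b = set_b[jb, , drop = FALSE],
       dist = d[cbind(ia, jb)],
       rejected = (nrow(set_a) - length(ia)) + (nrow(set_b) - length(jb)))
}

.cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Full second-order polynomial basis in (x, y, z): 10 terms per output axis.
# Inputs are centered and scaled before expansion for conditioning.
.poly2_basis <- function(p, center, scale) {
  q <- sweep(sweep(p, 2L, center), 2L, scale, "/")
  x <- q[, 1]; y <- q[, 2]; z <- q[, 3]
  cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
}

#' Fit a 3D second-order polynomial chromatic warp
#'
#' Least-squares fit of a full second-order polynomial (10 coefficients per
#' output axis, including cross terms) mapping channel-b points onto their
#' channel-a partners; this is the standard correction for residual
#' chromatic aberration between far-red dye channels after hardware
#' correction. Inputs are centered/scaled internally; the returned object
#' applies the back-transformation transparently.
#'
#' @param pairs result of [match_point_pairs()] (fields `a`, `b`).
#' @return object of class `poly_warp3d` with per-axis coefficients and
#'   median pair displacement before/after correction.
#' @export
fit_chromatic_warp <- function(pairs) {
  a <- pairs$a; b <- pairs$b
  if (nrow(b) < 30L)
    stop("need at least 30 matched pairs to fit 30 coefficients (got ",
         nrow(b), ")")
  center <- colMeans(b)
  scale <- apply(b, 2L, sd)
  scale[scale == 0] <- 1
  X <- .poly2_basis(b, center, scale)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient design (e.g. coplanar points): supply more, ",
         "better-spread pairs")
  coef <- qr.coef(qr_x, a)
  corrected <- X %*% coef
  before <- sqrt(rowSums((b - a)^2))
  after <- sqrt(rowSums((corrected - a)^2))
  structure(list(order = 2L, coefficients = coef, center = center,
                 scale = scale,
                 median_before = median(before), median_after = median(after),
                 fit_residual_median = median(after), n_pairs = nrow(b)),
            class = "poly_warp3d")
}

#' Apply a fitted chromatic warp to points
#' @param warp `poly_warp3d` from [fit_chromatic_warp()].
#' @param points numeric matrix (n x 3), nm.
#' @return corrected matrix (n x 3).
#' @export
apply_warp <- function(warp, points) {
  points <- as.matrix(points)
  out <- .poly2_basis(points, warp$center, warp$scale) %*% warp$coefficients
  dimnames(out) <- dimnames(points)
  out
}

#' Serialize / restore warp coefficients as JSON text
#' @param warp `poly_warp3d`.
#' @param path file path.
#' @export
write_warp <- function(warp, path) {
  obj <- list(order = warp$order,
              basis = "1,x,y,z,x2,y2,z2,xy,xz,yz (centered/scaled)",
              center = warp$center, scale = warp$scale,
              coefficients = warp$coefficients,
              median_before = warp$median_before,
              median_after = warp$median_after, n_pairs = warp$n_pairs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_warp
#' @export
read_warp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(order = obj$order,
                 coefficients = as.matrix(obj$coefficients),
                 center = obj$center, scale = obj$scale,
                 median_before = obj$median_before,
                 median_after = obj$median_after,
                 fit_residual_median = obj$median_after,
                 n_pairs = obj$n_pairs), class = "poly_warp3d")
}

#' @export
print.poly_warp3d <- function(x, ...) {
  cat(sprintf("<poly_warp3d> order 2, %d pairs; median displacement %.1f -> %.1f nm\n",
              x$n_pairs, x$median_before, x$median_after))
  invisible(x)
}

# Objective for one split of a chromosome's spots into two allele groups:
# total intra-group pairwise distance.
.allele_objective <- function(pts, grp) {
  obj <- 0
  for (g in 0:1) {
    m <- pts[grp == g, , drop = FALSE]
    if (nrow(m) > 1L) obj <- obj + sum(dist(m))
  }
  obj
}

#' Assign detected spots of one chromosome to two allele groups
#'
#' Chromatin-tracing probes do not encode parental identity, so the two
#' homologous alleles of each SE must be recovered geometrically: spots are
#' partitioned into two groups minimizing the total intra-group pairwise
#' distance, with the two spots of any doubly-detected SE forced into
#' different groups. Group labels (0/1) are arbitrary but stable. Small
#' instances (at most `exact_max` SEs on the chromosome) are solved by
#' exhaustive enumeration; larger ones by a deterministic heuristic (seed
#' from the farthest spot pair, greedy insertion, one swap-refinement pass).
#'
#' @param cell `cell_table` restricted to (or containing) one cell.
#' @param chromosome chromosome name.
#' @param cell_id optional cell to select when `cell` holds several.
#' @param exact_max exhaustive-search cutoff (number of SEs), default 12.
#' @return list with `assignment` (data.table: se_id, spot row, group),
#'   `objective_value` (nm) and `method`.
#' @export
assign_alleles <- function(cell, chromosome, cell_id = NULL, exact_max = 12L) {
  sp <- cell$spots
  if (!is.null(cell_id)) {
    sel <- which(sp$cell_id == cell_id)  # plain-R eval, outside `[`
    sp <- sp[sel]
  }
  chrom_se <- cell$loci$se_id[cell$loci$chrom == chromosome]
  sp <- sp[sp$se_id %in% chrom_se & sp$detected]
  if (nrow(sp) == 0L)
    return(list(assignment = data.table(se_id = character(), allele = integer(),
                                        group = integer()),
                objective_value = 0, method = "empty"))
  ses <- split(seq_len(nrow(sp)), sp$se_id)
  if (any(lengths(ses) > 2L))
    stop("more than 2 detected spots for an SE on ", chromosome)
  pts <- as.matrix(sp[, c("x", "y", "z")])
  n_se <- length(ses)
  assign_from_choice <- function(choice) {
    grp <- integer(nrow(sp))
    for (k in seq_along(ses)) {
      idx <- ses[[k]]
      if (length(idx) == 2L) {
        grp[idx[1]] <- choice[k]; grp[idx[2]] <- 1L - choice[k]
      } else grp[idx] <- choice[k]
    }
    grp
  }
  if (n_se <= exact_max) {
    # enumerate all 2^n SE-level choices; fix the first to break the label
    # symmetry of the two groups
    best <- NULL; best_obj <- Inf
    n_free <- n_se - 1L
    for (code in 0:(2^n_free - 1L)) {
      choice <- c(0L, as.integer(intToBits(code))[seq_len(max(n_free, 1L))][seq_len(n_free)])
      grp <- assign_from_choice(choice)
      obj <- .allele_objective(pts, grp)
      if (obj < best_obj) { best_obj <- obj; best <- grp }
    }
    grp <- best; method <- "exact"
  } else {
    grp <- .allele_greedy(pts, ses)
    method <- "greedy+swap"
    best_obj <- .allele_objective(pts, grp)
    # one pass of swap refinement over SEs
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in seq_along(ses)) {
        idx <- ses[[k]]
        g2 <- grp; g2[idx] <- 1L - g2[idx]
        obj2 <- .allele_objective(pts, g2)
        if (obj2 < best_obj - 1e-9) { grp <- g2; best_obj <- obj2; improved <- TRUE }
      }
    }
  }
  list(assignment = data.table(se_id = sp$se_id, allele = sp$allele,
                               row = seq_len(nrow(sp)), group = grp),
       objective_value = .allele_objective(pts, grp), method = method)
}

.allele_greedy <- function(pts, ses) {
  grp <- rep(NA_integer_, nrow(pts))
  # seed: the farthest pair of spots anchors the two groups
  dfull <- as.matrix(dist(pts))
  far <- which(dfull == max(dfull), arr.ind = TRUE)[1, ]
  grp[far[1]] <- 0L; grp[far[2]] <- 1L
  # honor the split constraint for the seed spots' SEs
  for (k in seq_along(ses)) {
    idx <- ses[[k]]
    if (length(idx) == 2L) {
      known <- idx[!is.na(grp[idx])]
      if (length(known) == 1L) grp[idx[idx != known]] <- 1L - grp[known]
    }
  }
  # greedy: SEs by decreasing spot separation, choose orientation adding the
  # least intra-group distance to already-placed spots
  order_se <- order(-vapply(ses, function(i)
    if (length(i) == 2L) dfull[i[1], i[2]] else 0, numeric(1)))
  added_cost <- function(i, g) {
    placed <- which(grp == g)
    if (!length(placed)) 0 else sum(dfull[i, placed])
  }
  for (k in order_se) {
    idx <- ses[[k]]
    if (!anyNA(grp[idx])) next
    if (length(idx) == 2L) {
      c0 <- added_cost(idx[1], 0L) + added_cost(idx[2], 1L)
      c1 <- added_cost(idx[1], 1L) + added_cost(idx[2], 0L)
      if (c0 <= c1) { grp[idx[1]] <- 0L; grp[idx[2]] <- 1L }
      else { grp[idx[1]] <- 1L; grp[idx[2]] <- 0L }
    } else {
      grp[idx] <- if (added_cost(idx, 0L) <= added_cost(idx, 1L)) 0L else 1L
    }
  }
  grp
}

#' Per-SE detection efficiency
#'
#' Fraction of cells in which both alleles of an SE were localized; the
#' denominator normalizing contact counts downstream. SEs below `floor` are
#' flagged as drop candidates (the assay's equivalent of probes removed for
#' low detection efficiency).
#'
#' @param table `cell_table`.
#' @param floor flag threshold, default 0.5.
#' @return list with `per_se` (data.table: se_id, both_allele_freq,
#'   spot_freq, flagged) and `overall_median`.
#' @export
detection_efficiency <- function(table, floor = 0.5) {
  sp <- table$spots
  per <- sp[, .(both_allele_freq = mean(tapply(detected, cell_id, all)),
                spot_freq = mean(detected)), by = se_id]
  per[, flagged := both_allele_freq < floor]
  list(per_se = per[], overall_median = median(per$both_allele_freq))
}

#' Replicate localization error
#'
#' 3D displacement magnitudes between repeated localizations of the same
#' loci (early vs late imaging rounds), quantifying accumulated drift,
#' degradation and camera noise.
#'
#' @param first,repeat_ numeric matrices (n x 3) of matched replicate
#'   localizations, same row order.
#' @return list with `displacements` (nm) and `median`.
#' @export
replicate_error <- function(first, repeat_) {
  first <- as.matrix(first); repeat_ <- as.matrix(repeat_)
  if (nrow(first) == 0L || nrow(first) != nrow(repeat_))
    stop("replicate sets must be non-empty and matched row-for-row")
  d <- sqrt(rowSums((first - repeat_)^2))
  list(displacements = d, median = median(d))
}
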