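# Partner-distribution entropy, triplet frequencies, cooperativity
# (observed/expected), odds ratios, and cross-method contact-map
# correlation. All cell-level statistics here run on a per-cell
# detection/adjacency summary (`proximity_events`), which can also be
# constructed directly from Bernoulli draws -- that is how the
# independence-null tests avoid the geometric correlations of real point
# configurations.

#' Per-cell SE detection and proximity events
#'
#' Collapses a `cell_table` to, per cell, which SEs were detected (any
#' allele) and which SE pairs had any detected spot pair within `radius`.
#' Proximity between the two homologous alleles of the same SE is not a
#' contact and is excluded. Triplet and cooperativity statistics consume
#' this object; restrict `se_subset` to keep the O(n^2 x cells) adjacency
#' array small.
#'
#' @param table `cell_table`.
#' @param radius nm.
#' @param se_subset optional character vector of SE ids to restrict to.
#' @return object of class `proximity_events`: `se_ids`, `det`
#'   (cells x n logical), `adj` (n x n x cells logical array).
#' @export
proximity_events <- function(table, radius, se_subset = NULL) {
  ids <- if (is.null(se_subset)) table$loci$se_id else se_subset
  stopifnot(all(ids %in% table$loci$se_id))
  sp <- table$spots[se_id %in% ids]
  cells <- unique(sp$cell_id)
  n <- length(ids)
  det <- matrix(FALSE, length(cells), n, dimnames = list(cells, ids))
  adj <- array(FALSE, c(n, n, length(cells)),
               dimnames = list(ids, ids, cells))
  for (k in seq_along(cells)) {
    cs <- sp[cell_id == cells[k]]
    di <- which(cs$detected)
    if (!length(di)) next
    det[k, match(unique(cs$se_id[di]), ids)] <- TRUE
    if (length(di) < 2L) next
    d <- .spot_dist(cs)[di, di, drop = FALSE]
    sid <- match(cs$se_id[di], ids)
    hit <- d < radius
    for (u in seq_along(di)) {
      vs <- unique(sid[which(hit[u, ])])
      vs <- vs[vs != sid[u]]  # homolog self-pairs excluded
      if (length(vs)) {
        adj[sid[u], vs, k] <- TRUE
        adj[vs, sid[u], k] <- TRUE
      }
    }
  }
  structure(list(se_ids = ids, det = det, adj = adj, radius = radius),
            class = "proximity_events")
}

#' Assemble proximity events from raw indicator arrays
#'
#' Constructor for synthetic event data (e.g. independent Bernoulli pair
#' events) bypassing any geometry.
#'
#' @param det cells x n logical detection matrix (colnames = SE ids).
#' @param adj n x n x cells logical adjacency array (symmetric slices).
#' @param radius nominal radius tag.
#' @return `proximity_events`.
#' @export
as_proximity_events <- function(det, adj, radius = NA_real_) {
  stopifnot(ncol(det) == dim(adj)[1], dim(adj)[1] == dim(adj)[2],
            nrow(det) == dim(adj)[3])
  structure(list(se_ids = colnames(det), det = det, adj = adj,
                 radius = radius), class = "proximity_events")
}

#' Contact-partner distribution of one SE
#'
#' The probability distribution `p(e)` of an SE's proximity partners across
#' cells: for each other SE `e`, the number of cells in which the pair was
#' proximate divided by the number of cells in which both were observed,
#' then normalized to sum to 1.
#'
#' @param table `cell_table` or `proximity_events`.
#' @param se_id the SE whose partners are profiled.
#' @param radius nm (default 600, the community scale); ignored when
#'   `table` is already a `proximity_events`.
#' @return list of class `partner_distribution`: `se_id`, `p` (named
#'   probabilities over other SEs, empty if the SE never had a partner),
#'   `n_obs` (total partner events).
#' @export
partner_distribution <- function(table, se_id, radius = 600) {
  ev <- if (inherits(table, "proximity_events")) table
        else proximity_events(table, radius)
  i <- match(se_id, ev$se_ids)
  if (is.na(i)) stop("unknown se_id: ", se_id)
  if (!any(ev$det[, i])) stop("SE never detected: ", se_id)
  others <- setdiff(seq_along(ev$se_ids), i)
  contacts <- vapply(others, function(j) sum(ev$adj[i, j, ]), numeric(1))
  codet <- vapply(others, function(j) sum(ev$det[, i] & ev$det[, j]), numeric(1))
  w <- ifelse(codet > 0, contacts / codet, 0)
  p <- if (sum(w) > 0) w / sum(w) else w
  names(p) <- ev$se_ids[others]
  structure(list(se_id = se_id, p = p, n_obs = sum(contacts),
                 empty = sum(contacts) == 0), class = "partner_distribution")
}

#' Shannon entropy of a partner distribution, in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log(0) = 0`. Zero means the
#' SE always partners with one specific SE; `log2(n)` means partnering is
#' uniform over all n candidates (fully promiscuous). An empty distribution
#' (no partner ever observed) is undefined and returns `NA` with a warning.
#'
#' @param p `partner_distribution` or a bare probability vector.
#' @return entropy in bits.
#' @export
entropy <- function(p) {
  if (inherits(p, "partner_distribution")) {
    if (p$empty) {
      warning("entropy undefined for an empty partner distribution")
      return(NA_real_)
    }
    p <- p$p
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("not a probability distribution")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Triplet proximity frequencies
#'
#' For each hub triplet (A, B, C; B the shared hub) the frequency, over
#' cells in which all three SEs were detected, of A-B and B-C both being
#' proximate (`definition = "hub"`, matching the cooperativity
#' construction). `"clique"` additionally requires A-C and is reported per
#' unordered triplet.
#'
#' @param table `cell_table` or `proximity_events`.
#' @param radius nm (default 600); ignored for `proximity_events` input.
#' @param definition `"hub"` or `"clique"`.
#' @return data.table: members (`a`, `hub`/`b`, `c`), `n_all3`, `n_hit`,
#'   `freq`, sorted by decreasing frequency.
#' @export
triplet_frequencies <- function(table, radius = 600,
                                definition = c("hub", "clique")) {
  definition <- match.arg(definition)
  ev <- if (inherits(table, "proximity_events")) table
        else proximity_events(table, radius)
  n <- length(ev$se_ids)
  if (n < 3L) stop("need at least 3 SEs")
  res <- list(); k <- 0L
  for (b in seq_len(n)) {
    rest <- setdiff(seq_len(n), b)
    for (ai in seq_len(length(rest) - 1L)) {
      for (ci in (ai + 1L):length(rest)) {
        a <- rest[ai]; cc <- rest[ci]
        if (definition == "clique" && a > b) next  # dedupe unordered
        all3 <- ev$det[, a] & ev$det[, b] & ev$det[, cc]
        hit <- ev$adj[a, b, ] & ev$adj[b, cc, ]
        if (definition == "clique") hit <- hit & ev$adj[a, cc, ]
        k <- k + 1L
        res[[k]] <- data.table(a = ev$se_ids[a], hub = ev$se_ids[b],
                               c = ev$se_ids[cc], n_all3 = sum(all3),
                               n_hit = sum(hit & all3))
      }
    }
  }
  out <- rbindlist(res)
  if (definition == "clique") {
    key <- apply(out[, .(a, hub, c)], 1L, function(r) paste(sort(r), collapse = "|"))
    out <- out[!duplicated(key)]
  }
  out[, freq := ifelse(n_all3 > 0, n_hit / n_all3, NA_real_)]
  setorder(out, -freq, na.last = TRUE)
  out[]
}

#' Triplet cooperativity (observed / expected)
#'
#' For a hub triplet (A, B, C): the pairwise proximity frequencies `p_ab`
#' and `p_bc` (each over cells where the pair was co-detected), the observed
#' frequency of joint A-B and B-C proximity (over cells where all three
#' were detected), and the ratio observed / expected with
#' `expected = p_ab * p_bc`. A ratio of 1 is expected when A-B and B-C
#' proximity are independent; cooperative assembly gives ratios > 1.
#'
#' @param table `cell_table` or `proximity_events`.
#' @param A,B,C distinct SE ids; B is the shared hub.
#' @param radius nm (default 600).
#' @return list of class `cooperativity_result`: `p_ab`, `p_bc`,
#'   `observed_abc`, `expected_abc`, `ratio`, `flagged`.
#' @export
cooperativity <- function(table, A, B, C, radius = 600) {
  stopifnot(length(unique(c(A, B, C))) == 3L)
  ev <- if (inherits(table, "proximity_events")) table
        else proximity_events(table, radius, se_subset = NULL)
  i <- match(c(A, B, C), ev$se_ids)
  if (anyNA(i)) stop("unknown SE id(s)")
  pair_freq <- function(u, v) {
    obs <- ev$det[, u] & ev$det[, v]
    if (!any(obs)) return(NA_real_)
    sum(ev$adj[u, v, ] & obs) / sum(obs)
  }
  p_ab <- pair_freq(i[1], i[2])
  p_bc <- pair_freq(i[2], i[3])
  all3 <- ev$det[, i[1]] & ev$det[, i[2]] & ev$det[, i[3]]
  if (!any(all3)) stop("SEs never co-detected in any cell")
  observed <- sum(ev$adj[i[1], i[2], ] & ev$adj[i[2], i[3], ] & all3) / sum(all3)
  expected <- p_ab * p_bc
  flagged <- is.na(expected) || expected == 0
  structure(list(triplet = c(A = A, B = B, C = C), p_ab = p_ab, p_bc = p_bc,
                 observed_abc = observed, expected_abc = expected,
                 ratio = if (flagged) NA_real_ else observed / expected,
                 flagged = flagged), class = "cooperativity_result")
}

#' Cooperativity catalog over all hub triplets
#'
#' @param ev `proximity_events`.
#' @return data.table: `a`, `hub`, `c`, `p_ab`, `p_bc`, `observed`,
#'   `expected`, `ratio` (NA when expected is 0 or any pair unobserved).
#' @export
cooperativity_catalog <- function(ev) {
  stopifnot(inherits(ev, "proximity_events"))
  n <- length(ev$se_ids)
  pair_p <- matrix(NA_real_, n, n)
  for (u in seq_len(n - 1L)) for (v in (u + 1L):n) {
    obs <- ev$det[, u] & ev$det[, v]
    if (any(obs)) {
      pair_p[u, v] <- pair_p[v, u] <- sum(ev$adj[u, v, ] & obs) / sum(obs)
    }
  }
  res <- list(); k <- 0L
  for (b in seq_len(n)) {
    rest <- setdiff(seq_len(n), b)
    for (ai in seq_len(length(rest) - 1L)) for (ci in (ai + 1L):length(rest)) {
      a <- rest[ai]; cc <- rest[ci]
      all3 <- ev$det[, a] & ev$det[, b] & ev$det[, cc]
      if (!any(all3)) next
      obs <- sum(ev$adj[a, b, ] & ev$adj[b, cc, ] & all3) / sum(all3)
      expd <- pair_p[a, b] * pair_p[b, cc]
      k <- k + 1L
      res[[k]] <- data.table(a = ev$se_ids[a], hub = ev$se_ids[b],
                             c = ev$se_ids[cc], p_ab = pair_p[a, b],
                             p_bc = pair_p[b, cc], observed = obs,
                             expected = expd,
                             ratio = if (is.na(expd) || expd == 0) NA_real_
                                     else obs / expd)
    }
  }
  rbindlist(res)
}

#' Odds ratio from a 2x2 contingency table
#'
#' `OR = (a * d) / (b * c)` with `a` = exposed & condition, `b` = exposed &
#' not, `c` = unexposed & condition, `d` = unexposed & not. With
#' `correction = "haldane"`, 0.5 is added to every cell whenever any cell is
#' zero (flagged in the output); without correction a zero `b * c` leaves
#' the OR undefined (`NA`, flagged).
#'
#' @param a,b,c,d nonnegative counts.
#' @param correction `"none"` or `"haldane"`.
#' @return list: `or`, `counts`, `corrected`, `flagged`.
#' @export
odds_ratio <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  counts <- c(a = a, b = b, c = c, d = d)
  corrected <- FALSE
  if (correction == "haldane" && any(counts == 0)) {
    counts <- counts + 0.5
    corrected <- TRUE
  }
  if (counts["b"] * counts["c"] == 0) {
    return(list(or = NA_real_, counts = counts, corrected = corrected,
                flagged = TRUE))
  }
  list(or = unname((counts["a"] * counts["d"]) / (counts["b"] * counts["c"])),
       counts = counts, corrected = corrected, flagged = FALSE)
}

#' Correlate two contact-frequency maps over cis pairs
#'
#' Pearson correlation between two locus-indexed contact maps (e.g. imaging
#' vs a sequencing-based assay), across upper-triangle pairs that are finite
#' in both maps; `scope = "cis"` restricts to same-chromosome pairs.
#'
#' @param map_a,map_b square matrices sharing a locus index.
#' @param chrom chromosome per locus (required for `scope = "cis"`).
#' @param scope `"cis"` or `"all"`.
#' @return list: `r`, `n_pairs`.
#' @export
correlate_contact_maps <- function(map_a, map_b, chrom = NULL,
                                   scope = c("cis", "all")) {
  scope <- match.arg(scope)
  stopifnot(all(dim(map_a) == dim(map_b)))
  n <- nrow(map_a)
  ut <- upper.tri(map_a)
  keep <- ut & is.finite(map_a) & is.finite(map_b)
  if (scope == "cis") {
    if (is.null(chrom)) stop("cis scope requires per-locus chromosomes")
    same <- outer(chrom, chrom, "==")
    keep <- keep & same
  }
  if (sum(keep) < 3L) stop("fewer than 3 shared finite pairs")
  list(r = cor(map_a[keep], map_b[keep]), n_pairs = sum(keep))
}
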