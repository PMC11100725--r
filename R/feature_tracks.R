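# Per-SE genomic/epigenomic predictors: interval coverage from bedGraph
# tracks, DamID lamina-association window scores, SPRITE speckle
# association, and genomic tether metrics computed from the locus table
# itself.

#' Read a bedGraph-like track
#'
#' Four tab-separated columns `chrom, start, end, value` (0-based half-open,
#' no header or a `track`/`#` header line). Used here as the text
#' representation of coverage tracks (the binary bigWig originals are out of
#' scope).
#'
#' @param path file path.
#' @param genome_build build tag attached to the track (default "mm10").
#' @return `data.table` of class `genomic_track` with attribute
#'   `genome_build`.
#' @export
read_bedgraph <- function(path, genome_build = "mm10") {
  raw <- fread(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "value"),
               skip = if (grepl("^(track|#)", readLines(path, n = 1L))) 1L else 0L)
  if (!is.numeric(raw$value) || any(!is.finite(raw$value)))
    stop("bedGraph values must be finite numbers: ", path)
  genomic_track(raw, genome_build)
}

#' @rdname read_bedgraph
#' @param intervals data.frame with `chrom`, `start`, `end`, `value`.
#' @export
genomic_track <- function(intervals, genome_build = "mm10") {
  dt <- as.data.table(intervals)[, .(chrom, start, end, value)]
  setorder(dt, chrom, start)
  # normalize: truncate any interval at the start of the next one on the
  # same chromosome, then drop empty intervals
  dt[, end := pmin(end, c(start[-1], Inf)), by = chrom]
  dt <- dt[end > start]
  setattr(dt, "genome_build", genome_build)
  setattr(dt, "class", c("genomic_track", class(dt)))
  dt[]
}

.check_build <- function(track, loci) {
  tb <- attr(track, "genome_build")
  lb <- attr(loci, "genome_build")
  if (!is.null(tb) && !is.null(lb) && !identical(tb, lb))
    stop("genome build mismatch: track is ", tb, ", loci are ", lb)
}

.track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1L,
                                          end = track$end))
}

#' Signal coverage over SE intervals
#'
#' Per SE, the sum of `value x overlap-length` over all track intervals
#' intersecting the SE region, optionally scaled by total track signal
#' ("per million" library-size normalization). Coverage is linear in the
#' track: scaling every value by k scales every pre-normalization per-SE
#' value by k.
#'
#' @param track `genomic_track`.
#' @param loci `se_locus_table`.
#' @param normalize divide by total track signal and multiply by 1e6
#'   (default FALSE: raw value-length sums).
#' @return numeric vector, one value per locus row (0 where no overlap).
#' @export
coverage_over_intervals <- function(track, loci, normalize = FALSE) {
  .check_build(track, loci)
  gr_t <- .track_granges(track)
  gr_l <- loci_to_granges(loci)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_t)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    gr_l[S4Vectors::queryHits(hits)], gr_t[S4Vectors::subjectHits(hits)]))
  val <- track$value[S4Vectors::subjectHits(hits)] * w
  out <- rep(0, nrow(loci))
  agg <- tapply(val, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  if (normalize) {
    total <- sum(track$value * (track$end - track$start))
    if (total == 0) stop("cannot normalize: total track signal is 0")
    out <- out / total * 1e6
  }
  out
}

#' DamID window score around each SE
#'
#' For each SE, the track bin with the largest overlap anchors a window of
#' `window` bp centered on that bin's midpoint, and the mean of bin values
#' whose midpoints fall inside the window is returned (a 30 kb window on a
#' 10 kb-binned track averages the anchor bin and its two neighbors; the
#' widening compensates for data sparsity). SEs with no overlapping bin get
#' `NA` and a warning.
#'
#' @param track binned `genomic_track` (e.g. 10 kb bins).
#' @param loci `se_locus_table`.
#' @param window window width in bp, default 30000.
#' @return numeric vector per locus row (NA where no bin overlaps).
#' @export
damid_window_score <- function(track, loci, window = 30000) {
  .check_build(track, loci)
  gr_t <- .track_granges(track)
  gr_l <- loci_to_granges(loci)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_t)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    gr_l[S4Vectors::queryHits(hits)], gr_t[S4Vectors::subjectHits(hits)]))
  out <- rep(NA_real_, nrow(loci))
  mid <- (track$start + track$end) / 2
  for (q in unique(S4Vectors::queryHits(hits))) {
    rows <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]
    anchor <- rows[which.max(w[S4Vectors::queryHits(hits) == q])]
    inwin <- track$chrom == track$chrom[anchor] &
      abs(mid - mid[anchor]) <= window / 2
    out[q] <- mean(track$value[inwin])
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " locus/loci without any overlapping bin")
  out
}

#' Read a SPRITE cluster file
#'
#' Plain-text format, one cluster per line with three tab-separated fields:
#' cluster barcode; comma-separated RNA species names (`.` if none);
#' comma-separated DNA reads as `chrom:position`.
#'
#' @param path file path.
#' @return list of clusters, each `list(barcode, rnas, dna)` with `dna` a
#'   data.table (chrom, pos).
#' @export
read_sprite_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SPRITE cluster file: ", path)
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed SPRITE cluster line: ", l)
    rnas <- if (f[2] == ".") character() else strsplit(f[2], ",")[[1]]
    dna <- if (f[3] == ".") data.table(chrom = character(), pos = integer())
    else {
      parts <- strsplit(strsplit(f[3], ",")[[1]], ":", fixed = TRUE)
      data.table(chrom = vapply(parts, `[`, "", 1L),
                 pos = as.integer(vapply(parts, `[`, "", 2L)))
    }
    list(barcode = f[1], rnas = rnas, dna = dna)
  })
}

# RNAs whose presence marks a cluster as speckle-associated
.speckle_rnas_default <- c("Malat1", "U1.snRNA", "U2.snRNA", "U4.snRNA",
                           "U6.snRNA")

#' Speckle association from RNA-DNA SPRITE clusters
#'
#' Clusters are filtered to those containing at least one speckle-resident
#' RNA and at most `max_dna` DNA loci (very large clusters are fragments of
#' whole nuclei); the genomic positions of their unique DNA reads are then
#' summed genome-wide in `bin`-sized bins. The two filters commute.
#'
#' @param clusters list from [read_sprite_clusters()].
#' @param speckle_rnas RNA names defining speckle association.
#' @param max_dna maximum DNA loci per retained cluster, default 100.
#' @param bin bin width in bp, default 250000.
#' @return data.table: `chrom`, `bin_start`, `count`.
#' @export
speckle_association <- function(clusters, speckle_rnas = .speckle_rnas_default,
                                max_dna = 100, bin = 250000) {
  if (!length(clusters)) stop("empty cluster list")
  keep <- Filter(function(cl)
    any(cl$rnas %in% speckle_rnas) && nrow(cl$dna) <= max_dna, clusters)
  if (!length(keep))
    return(data.table(chrom = character(), bin_start = integer(),
                      count = integer()))
  reads <- rbindlist(lapply(keep, function(cl) unique(cl$dna)))
  reads[, bin_start := as.integer(pos %/% bin * bin)]
  reads[, .(count = .N), by = .(chrom, bin_start)][order(chrom, bin_start)]
}

#' Per-SE score from binned counts
#'
#' Maps per-bin counts (e.g. speckle association) onto loci: each SE takes
#' the count of the bin with the largest overlap of its interval (0 when no
#' bin has reads).
#'
#' @param bins data.table from [speckle_association()].
#' @param loci `se_locus_table`.
#' @param bin bin width used to build `bins`.
#' @return numeric vector per locus row.
#' @export
bin_score_per_locus <- function(bins, loci, bin = 250000) {
  out <- numeric(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    cand <- bins[chrom == loci$chrom[i] &
                 bin_start < loci$end[i] & bin_start + bin > loci$start[i]]
    if (!nrow(cand)) next
    ov <- pmin(cand$bin_start + bin, loci$end[i]) -
      pmax(cand$bin_start, loci$start[i])
    out[i] <- cand$count[which.max(ov)]
  }
  out
}

#' Genomic tether metrics
#'
#' Linear-genome predictors of spatial clustering: for each SE, the number
#' of other SEs whose centers lie within 1 Mb on the same chromosome
#' (`n_se_1mb`), and the sum over all other cis SEs of the inverse
#' center-to-center distance in Mb (`inv_dist_sum`, 1/Mb). Trans SEs have
#' no genomic distance and are excluded. Both metrics are symmetric for any
#' pair.
#'
#' @param loci `se_locus_table` (dropped loci excluded).
#' @param max_dist window for `n_se_1mb`, default 1e6 bp.
#' @return data.table: `se_id`, `n_se_1mb`, `inv_dist_sum`.
#' @export
tether_metrics <- function(loci, max_dist = 1e6) {
  lo <- as.data.table(loci)
  if ("dropped" %in% names(lo)) lo <- lo[dropped == FALSE]
  n <- nrow(lo)
  n_1mb <- integer(n); inv_sum <- numeric(n)
  for (ch in unique(lo$chrom)) {
    idx <- which(lo$chrom == ch)
    if (length(idx) < 2L) next
    d <- abs(outer(lo$center[idx], lo$center[idx], "-"))
    diag(d) <- NA
    n_1mb[idx] <- rowSums(d <= max_dist, na.rm = TRUE)
    inv_sum[idx] <- rowSums(1 / (d / 1e6), na.rm = TRUE)
  }
  data.table(se_id = lo$se_id, n_se_1mb = n_1mb, inv_dist_sum = inv_sum)
}

#' Assemble the per-SE feature table
#'
#' One row per non-dropped SE: ChIP coverage values (one column per named
#' track), the DamID window score, the speckle bin score, and the tether
#' metrics. Remaining missing values (e.g. SEs outside all DamID bins) are
#' imputed with the column median and reported.
#'
#' @param loci `se_locus_table`.
#' @param chip_tracks named list of `genomic_track`s (e.g. pol2, med1,
#'   oct4, sox2, nanog, k27ac).
#' @param damid_track optional binned `genomic_track` of LAD scores.
#' @param speckle_bins optional data.table from [speckle_association()].
#' @param normalize_chip normalize ChIP coverage by total track signal.
#' @return data.table keyed by `se_id` with feature columns and `chrom`.
#' @export
build_feature_table <- function(loci, chip_tracks = list(),
                                damid_track = NULL, speckle_bins = NULL,
                                normalize_chip = TRUE) {
  lo <- as.data.table(loci)[dropped == FALSE]
  lo_tbl <- se_locus_table(lo)
  ft <- data.table(se_id = lo$se_id)
  for (nm in names(chip_tracks))
    set(ft, j = nm, value = coverage_over_intervals(chip_tracks[[nm]], lo_tbl,
                                                    normalize = normalize_chip))
  if (!is.null(damid_track))
    ft[, lad_score := damid_window_score(damid_track, lo_tbl)]
  if (!is.null(speckle_bins))
    ft[, speckle_score := bin_score_per_locus(speckle_bins, lo_tbl)]
  tm <- tether_metrics(lo_tbl)
  ft[, `:=`(n_se_1mb = tm$n_se_1mb, inv_dist_sum = tm$inv_dist_sum,
            chrom = lo$chrom)]
  num <- setdiff(names(ft)[vapply(ft, is.numeric, TRUE)], "se_id")
  for (nm in num) {
    if (anyNA(ft[[nm]])) {
      n_imp <- sum(is.na(ft[[nm]]))
      ft[is.na(get(nm)), (nm) := median(ft[[nm]], na.rm = TRUE)]
      message("imputed ", n_imp, " missing value(s) in feature '", nm,
              "' with the column median")
    }
  }
  ft[]
}
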