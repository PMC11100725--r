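#' @import data.table
#' @importFrom stats median quantile sd cor complete.cases rnorm runif rbinom
#'   rlnorm dist optim setNames qlogis plogis cor.test ks.test
#' @importFrom utils head tail
NULL

# Internal: columns every locus table carries, in canonical order.
.locus_cols <- c("se_id", "name", "chrom", "start", "end", "center",
                 "linked_gene", "rank_suffix", "dropped")

#' Construct and validate an SE locus table
#'
#' An SE locus table is a `data.table` with one row per super-enhancer (SE)
#' probe target: a stable `se_id`, a gene-linked `name` (e.g. `"Nanog-0"`),
#' 0-based half-open genomic coordinates (`chrom`, `start`, `end`), the
#' interval `center`, the `linked_gene` symbol, an optional `rank_suffix`
#' (ranked genomic proximity of the SE to its gene, 0 = promoter-overlapping)
#' and a `dropped` flag. Dropped loci (e.g. probes removed for low detection
#' efficiency) are retained and flagged rather than deleted, so locus counts
#' stay auditable.
#'
#' @param x data.frame with at least `chrom`, `start`, `end`, `name`.
#' @return A `se_locus_table` (also a `data.table`).
#' @export
se_locus_table <- function(x) {
  dt <- as.data.table(x)
  need <- c("chrom", "start", "end", "name")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("locus table missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"se_id" %in% names(dt)) dt[, se_id := name]
  if (!"linked_gene" %in% names(dt)) dt[, linked_gene := sub("-[0-9]+$", "", name)]
  if (!"rank_suffix" %in% names(dt)) {
    rk <- suppressWarnings(as.integer(sub("^.*-([0-9]+)$", "\\1", dt$name)))
    rk[!grepl("-[0-9]+$", dt$name)] <- NA_integer_
    dt[, rank_suffix := rk]
  }
  if (!"dropped" %in% names(dt)) dt[, dropped := FALSE]
  dt[, dropped := as.logical(dropped)]
  dt[, `:=`(start = as.numeric(start), end = as.numeric(end))]
  if (anyNA(dt$start) || anyNA(dt$end))
    stop("locus table: non-numeric start/end coordinate")
  bad <- which(dt$end < dt$start)
  if (length(bad))
    stop("locus table: end < start at row(s) ", paste(head(bad, 5), collapse = ", "))
  if (any(dt$start < 0))
    stop("locus table: negative start coordinate")
  if (!"center" %in% names(dt) || anyNA(dt$center))
    dt[, center := floor((start + end) / 2)]
  setcolorder(dt, intersect(.locus_cols, names(dt)))
  setattr(dt, "class", c("se_locus_table", class(dt)))
  dt[]
}

#' Read an SE locus table from a BED-like TSV
#'
#' Expects tab-separated columns `chrom, start, end, name` with optional
#' `gene`, `rank`, `dropped` columns (header optional; BED column order is
#' assumed when no header names are present). Coordinates are interpreted as
#' 0-based half-open, the BED convention.
#'
#' @param path file path.
#' @return `se_locus_table`.
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L || nrow(raw <- tryCatch(
        fread(path, sep = "\t", header = "auto"),
        error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))) == 0L) {
    warning("empty locus table: ", path)
    return(se_locus_table(data.table(chrom = character(), start = numeric(),
                                     end = numeric(), name = character())))
  }
  if (all(grepl("^V[0-9]+$", names(raw)))) {
    bed_names <- c("chrom", "start", "end", "name", "score", "strand",
                   "gene", "rank", "dropped")
    setnames(raw, names(raw), bed_names[seq_along(names(raw))])
  }
  if ("gene" %in% names(raw)) setnames(raw, "gene", "linked_gene")
  if ("rank" %in% names(raw)) setnames(raw, "rank", "rank_suffix")
  if (!is.numeric(raw$start) || !is.numeric(raw$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$start))) |
                 is.na(suppressWarnings(as.numeric(raw$end))))
    stop("parse error in ", path, ": non-numeric coordinates at data line(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  se_locus_table(raw)
}

#' Write an SE locus table as BED-like TSV
#' @param loci `se_locus_table`.
#' @param path output path.
#' @export
write_locus_table <- function(loci, path) {
  out <- as.data.table(loci)[, .(chrom, start = as.integer(start),
                                 end = as.integer(end), name,
                                 gene = linked_gene, rank = rank_suffix,
                                 dropped = dropped, se_id = se_id)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Standardize a probe target region around a center coordinate
#'
#' Every SE probe targets a standardized 15 kb region: 7.5 kb on either side
#' of the published SE center. Centers closer than 7.5 kb to the chromosome
#' start are clipped at 0 (with a warning), so clipped regions are shorter.
#'
#' @param center base-pair center (vectorized).
#' @param half_width half of the standardized width, default 7500 bp.
#' @return matrix with columns `start`, `end`.
#' @export
standardize_region <- function(center, half_width = 7500) {
  start <- center - half_width
  if (any(start < 0)) {
    warning("center < ", half_width, " bp: region clipped at 0")
    start <- pmax(start, 0)
  }
  cbind(start = start, end = center + half_width)
}

#' Merge genomically proximal SE loci
#'
#' Loci on the same chromosome whose standardized regions lie within
#' `max_gap` of each other are merged into a single locus spanning their
#' union (the historical example being adjacent histone-cluster SEs merged
#' under one label). Merged loci take a supplied name, else the member names
#' joined by `"+"`. `dropped` is the logical AND of the members.
#'
#' @param loci `se_locus_table`, sorted by (chrom, start).
#' @param max_gap maximum gap (bp) between regions to trigger a merge;
#'   default 15000.
#' @param merged_names optional named character vector mapping the name of
#'   the first member of a merged run to the label the merge should take.
#' @return `se_locus_table` with merged rows.
#' @export
merge_proximal_loci <- function(loci, max_gap = 15000, merged_names = NULL) {
  dt <- as.data.table(loci)[, intersect(.locus_cols, names(loci)), with = FALSE]
  setorder(dt, chrom, start)
  if (nrow(dt) <= 1L) return(se_locus_table(dt))
  grp <- integer(nrow(dt)); grp[1] <- 1L
  for (i in 2:nrow(dt)) {
    same <- dt$chrom[i] == dt$chrom[i - 1L] &&
      dt$start[i] - dt$end[i - 1L] <= max_gap
    grp[i] <- if (same) grp[i - 1L] else grp[i - 1L] + 1L
  }
  merged <- dt[, {
    if (.N == 1L) .SD else {
      nm <- if (!is.null(merged_names) && name[1] %in% names(merged_names))
        unname(merged_names[name[1]]) else paste(name, collapse = "+")
      data.table(se_id = paste(se_id, collapse = "+"), name = nm,
                 chrom = chrom[1], start = min(start), end = max(end),
                 center = floor((min(start) + max(end)) / 2),
                 linked_gene = linked_gene[1],
                 rank_suffix = rank_suffix[1], dropped = all(dropped))
    }
  }, by = .(.grp = grp)][, .grp := NULL]
  se_locus_table(merged[])
}

#' Convert a locus table to GRanges
#' @param loci `se_locus_table`.
#' @return `GRanges` with 1-based coordinates (converted at the boundary)
#'   and metadata columns `se_id`, `name`, `dropped`.
#' @export
loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    se_id = loci$se_id, name = loci$name, dropped = loci$dropped)
}

# ---- CellTable -------------------------------------------------------------

.spot_cols <- c("cell_id", "fov_id", "se_id", "allele", "x", "y", "z",
                "detected", "quality")

#' Construct a CellTable of 3D spot records
#'
#' A `cell_table` bundles all spot records of a dataset with the locus table
#' they refer to. Each spot is one (cell, SE, allele) localization with
#' nanometer coordinates; `detected = FALSE` spots carry `NA` coordinates
#' (never 0). A complete diploid cell contributes exactly two spots per
#' non-dropped locus.
#'
#' @param spots data.frame of spot records (see Details for columns).
#' @param loci `se_locus_table` resolving every `se_id` in `spots`.
#' @param meta named list of provenance (seed, units, generator settings).
#' @return `cell_table` object.
#' @export
cell_table <- function(spots, loci, meta = list()) {
  sp <- as.data.table(spots)
  miss <- setdiff(c("cell_id", "se_id", "allele", "x", "y", "z"), names(sp))
  if (length(miss))
    stop("spot table missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"fov_id" %in% names(sp)) sp[, fov_id := "fov0"]
  if (!"detected" %in% names(sp)) sp[, detected := is.finite(x) & is.finite(y) & is.finite(z)]
  if (!"quality" %in% names(sp)) sp[, quality := 1]
  sp[, allele := as.integer(allele)]
  if (!all(sp$allele %in% c(0L, 1L))) stop("allele must be 0 or 1")
  unknown <- setdiff(unique(sp$se_id), loci$se_id)
  if (length(unknown))
    stop("spot se_id not in locus table: ", paste(head(unknown, 5), collapse = ", "))
  if (anyDuplicated(sp[, .(cell_id, se_id, allele)]))
    stop("duplicate (cell_id, se_id, allele) spot records")
  bad <- sp$detected & !(is.finite(sp$x) & is.finite(sp$y) & is.finite(sp$z))
  if (any(bad)) stop("detected spots with non-finite coordinates")
  sp[detected == FALSE, c("x", "y", "z") := NA_real_]
  setcolorder(sp, .spot_cols)
  meta$units <- meta$units %||% "nm"
  structure(list(spots = sp[], loci = loci, meta = meta), class = "cell_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d loci (%d dropped), %d spots (%.1f%% detected)\n",
              length(unique(x$spots$cell_id)), nrow(x$loci), sum(x$loci$dropped),
              nrow(x$spots), 100 * mean(x$spots$detected)))
  invisible(x)
}

#' Cell identifiers of a cell_table
#' @param table `cell_table`.
#' @export
cell_ids <- function(table) unique(table$spots$cell_id)

# FOF-CT-style core column order; coordinates stay in nanometers (declared
# in the header) -- this package never converts spatial units implicitly.
.fofct_cols <- c("Spot_ID", "Trace_ID", "X", "Y", "Z", "Chrom",
                 "Chrom_Start", "Chrom_End", "Cell_ID", "Extra_Cell_ROI_ID",
                 "Allele", "SE_ID", "Detected", "Quality")

#' Write a spot table
#'
#' Two dialects are supported: `"flat_tsv"` (the package's native tidy
#' layout, one row per spot) and `"fofct_core"` (a FOF-CT-style core spot
#' table with `##`-prefixed header lines and the standard column order).
#' Coordinates are written at fixed 3-decimal precision so a write/read
#' round trip is exact at that precision; undetected spots keep an explicit
#' `NA` sentinel.
#'
#' @param table `cell_table`.
#' @param path output path.
#' @param dialect `"flat_tsv"` or `"fofct_core"`.
#' @export
write_spot_table <- function(table, path, dialect = c("flat_tsv", "fofct_core")) {
  dialect <- match.arg(dialect)
  sp <- copy(table$spots)
  fmt <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.3f", v))
  sp[, c("x", "y", "z") := lapply(.SD, fmt), .SDcols = c("x", "y", "z")]
  if (dialect == "flat_tsv") {
    fwrite(sp, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    li <- table$loci[match(sp$se_id, table$loci$se_id)]
    out <- data.table(
      Spot_ID = sprintf("%s_%s_a%d", sp$cell_id, sp$se_id, sp$allele),
      Trace_ID = sprintf("%s_a%d", sp$cell_id, sp$allele),
      X = sp$x, Y = sp$y, Z = sp$z,
      Chrom = li$chrom, Chrom_Start = as.integer(li$start),
      Chrom_End = as.integer(li$end), Cell_ID = sp$cell_id,
      Extra_Cell_ROI_ID = sp$fov_id, Allele = sp$allele, SE_ID = sp$se_id,
      Detected = as.integer(sp$detected), Quality = sp$quality)
    writeLines(c("##FOF-CT_version=core_v0.1 (dialect: secom)",
                 "##XYZ_unit=nm",
                 paste0("##columns=(", paste(.fofct_cols, collapse = ","), ")")),
               path)
    suppressWarnings(fwrite(out, path, sep = "\t", na = "NA", quote = FALSE,
                            append = TRUE, col.names = TRUE))
  }
  invisible(path)
}

#' Read a spot table
#' @param path file path.
#' @param loci `se_locus_table`; required for `flat_tsv`, reconstructed from
#'   the embedded locus columns for `fofct_core` when omitted.
#' @param dialect `"flat_tsv"` or `"fofct_core"`.
#' @return `cell_table`.
#' @export
read_spot_table <- function(path, loci = NULL, dialect = c("flat_tsv", "fofct_core")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_tsv") {
    sp <- fread(path, sep = "\t", na.strings = "NA")
    miss <- setdiff(c("cell_id", "se_id", "allele", "x", "y", "z"), names(sp))
    if (length(miss))
      stop("spot table ", path, " missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    if (is.null(loci)) stop("flat_tsv dialect requires a locus table")
    cell_table(sp, loci)
  } else {
    hdr <- readLines(path, n = 10L)
    n_skip <- sum(startsWith(hdr, "##"))
    raw <- fread(path, sep = "\t", skip = n_skip, na.strings = "NA")
    miss <- setdiff(c("Spot_ID", "Trace_ID", "X", "Y", "Z", "Cell_ID",
                      "Allele", "SE_ID"), names(raw))
    if (length(miss))
      stop("FOF-CT table ", path, " missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    sp <- data.table(cell_id = raw$Cell_ID,
                     fov_id = raw$Extra_Cell_ROI_ID %||% "fov0",
                     se_id = raw$SE_ID, allele = raw$Allele,
                     x = raw$X, y = raw$Y, z = raw$Z,
                     detected = if ("Detected" %in% names(raw))
                       as.logical(raw$Detected) else is.finite(raw$X),
                     quality = raw$Quality %||% 1)
    if (is.null(loci)) {
      lo <- unique(data.table(se_id = raw$SE_ID, name = raw$SE_ID,
                              chrom = raw$Chrom, start = raw$Chrom_Start,
                              end = raw$Chrom_End))
      loci <- se_locus_table(lo)
    }
    cell_table(sp, loci)
  }
}
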