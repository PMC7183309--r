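# Interval arithmetic, peak-to-gene assignment and coverage signal.
#
# Containers are GRanges (1-based, closed, the R convention); every
# file boundary (BED, bedGraph) and the gintervals()/as_bed_df()
# constructors speak the 0-based half-open BED convention, and GFF
# input is converted on read by rtracklayer. Coverage scores are read
# densities in reads per bp, so integrating score * bp over a region
# yields a read count.

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom chromosome labels
#' @param start0,end0 0-based half-open interval bounds,
#'   `0 <= start0 < end0`
#' @param strand `"+"`, `"-"` or `"."` (unstranded)
#' @param name optional interval names (stored in the `name` column)
#' @param seqlengths optional named chromosome lengths for bounds
#'   checking and clipping
#' @return a GRanges
#' @export
gintervals <- function(chrom, start0, end0, strand = ".", name = NULL,
                       seqlengths = NULL) {
  if (any(start0 < 0) || any(start0 >= end0))
    stop_config("intervals must satisfy 0 <= start < end")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = strand)
  if (!is.null(name)) gr$name <- as.character(name)
  if (!is.null(seqlengths)) {
    sl <- seqlengths[GenomeInfoDb::seqlevels(gr)]
    if (anyNA(sl))
      stop_config("interval on chromosome absent from seqlengths")
    if (any(end0 > seqlengths[as.character(chrom)]))
      stop_config("interval end exceeds chromosome length")
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  gr
}

#' Convert a GRanges back to a 0-based half-open table
#'
#' @param gr a GRanges
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (BED-style coordinates) plus any extra metadata columns
#' @export
as_bed_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
  extra <- S4Vectors::mcols(gr)
  extra <- extra[, setdiff(colnames(extra), "name"), drop = FALSE]
  cbind(df, as.data.frame(extra))
}

#' Strand-aware promoter windows around transcription start sites
#'
#' The TSS is the start of a `+` gene and the end of a `-` gene; the
#' window extends `upstream` bp against the direction of transcription
#' and `downstream` bp with it, clipped at chromosome bounds when
#' lengths are known. The defaults (-2000/+500) are an explicit,
#' configurable choice: "promoter" has no single accepted width.
#'
#' @param genes stranded GRanges of gene bodies
#' @param upstream,downstream window extents in bp
#' @param unstranded policy for `*` strands: `"error"` (default) or
#'   `"both-sides"` (symmetric `upstream` on both sides of the start)
#' @return GRanges of promoter windows, same order and names as input
#' @export
promoter_windows <- function(genes, upstream = 2000, downstream = 500,
                             unstranded = c("error", "both-sides")) {
  unstranded <- match.arg(unstranded)
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*") && unstranded == "error")
    stop_config("unstranded gene(s) at index %s; use unstranded = \"both-sides\"",
                paste(utils::head(which(str == "*"), 5), collapse = ", "))
  out <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = upstream,
                             downstream = downstream))
  if (any(str == "*")) {
    # symmetric window around the interval start for unstranded genes
    i <- which(str == "*")
    GenomicRanges::ranges(out)[i] <- IRanges::IRanges(
      start = GenomicRanges::start(genes)[i] - as.integer(upstream),
      end = GenomicRanges::start(genes)[i] + as.integer(upstream) - 1L)
  }
  # clip at chromosome bounds (always at 1; at seqlengths when known)
  sl <- GenomeInfoDb::seqlengths(out)
  st <- pmax(GenomicRanges::start(out), 1L)
  en <- GenomicRanges::end(out)
  known <- !is.na(sl[as.character(GenomicRanges::seqnames(out))])
  if (any(known))
    en[known] <- pmin(en[known],
                      sl[as.character(GenomicRanges::seqnames(out))[known]])
  GenomicRanges::ranges(out) <- IRanges::IRanges(start = st, end = en)
  out
}

#' All overlapping interval pairs with overlap lengths
#'
#' Strand-blind overlap of two interval sets (half-open semantics:
#' abutting intervals do not overlap). Backed by the interval-tree
#' overlap machinery of GenomicRanges.
#'
#' @param a,b GRanges
#' @return data.frame with `a_idx`, `b_idx` (indices into the inputs),
#'   `chrom`, `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open) and `overlap_bp`, sorted by (chrom, a_start, b_start)
#' @export
intersect_intervals <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(a)[ai], GenomicRanges::end(b)[bi]) -
    pmax(GenomicRanges::start(a)[ai], GenomicRanges::start(b)[bi]) + 1L
  out <- data.frame(
    a_idx = ai, b_idx = bi,
    chrom = as.character(GenomicRanges::seqnames(a))[ai],
    a_start = GenomicRanges::start(a)[ai] - 1L,
    a_end = GenomicRanges::end(a)[ai],
    b_start = GenomicRanges::start(b)[bi] - 1L,
    b_end = GenomicRanges::end(b)[bi],
    overlap_bp = as.integer(ov))
  out <- out[order(out$chrom, out$a_start, out$b_start, out$a_idx, out$b_idx), ]
  rownames(out) <- NULL
  out
}

#' Assign ChIP peaks to genes by symbol or by promoter overlap
#'
#' In `"symbol"` mode peaks must carry a `gene_symbol` column; the
#' join is an exact match after case normalization (symbols are
#' uppercased on both sides). In `"interval"` mode a peak is assigned
#' to every gene whose promoter window contains the peak summit — a
#' summit inside two overlapping windows maps to both genes.
#'
#' @param peaks GRanges with a 0-based `summit` offset column
#'   (required in interval mode) and optionally `gene_symbol`
#' @param genes stranded GRanges with a `name` column
#' @param mode `"interval"` or `"symbol"`
#' @param upstream,downstream promoter window passed to
#'   [promoter_windows()] (interval mode)
#' @return data.frame `gene`, `peak`, `peak_chrom`, `peak_start`,
#'   `peak_end` (0-based half-open), sorted by (gene, chrom, start)
#' @export
map_peaks_to_genes <- function(peaks, genes,
                               mode = c("interval", "symbol"),
                               upstream = 2000, downstream = 500) {
  mode <- match.arg(mode)
  peak_name <- peaks$name %||% sprintf("peak%03d", seq_along(peaks))
  if (mode == "symbol") {
    if (is.null(peaks$gene_symbol))
      stop_config(paste("peaks carry no gene_symbol annotation;",
                        "use mode = \"interval\""))
    gi <- match(norm_symbols(peaks$gene_symbol), norm_symbols(genes$name))
    keep <- !is.na(gi)
    out <- data.frame(
      gene = genes$name[gi[keep]],
      peak = peak_name[keep],
      peak_chrom = as.character(GenomicRanges::seqnames(peaks))[keep],
      peak_start = GenomicRanges::start(peaks)[keep] - 1L,
      peak_end = GenomicRanges::end(peaks)[keep])
  } else {
    if (is.null(peaks$summit))
      stop_config("interval mode requires a summit column on peaks")
    win <- promoter_windows(genes, upstream, downstream)
    summits <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(peaks),
      IRanges::IRanges(start = GenomicRanges::start(peaks) + peaks$summit,
                       width = 1L))
    hits <- GenomicRanges::findOverlaps(summits, win, ignore.strand = TRUE)
    pi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    out <- data.frame(
      gene = genes$name[gi],
      peak = peak_name[pi],
      peak_chrom = as.character(GenomicRanges::seqnames(peaks))[pi],
      peak_start = GenomicRanges::start(peaks)[pi] - 1L,
      peak_end = GenomicRanges::end(peaks)[pi])
  }
  out <- out[order(out$gene, out$peak_chrom, out$peak_start, out$peak), ]
  rownames(out) <- NULL
  out
}

#' Coverage track container
#'
#' Sorted, non-overlapping scored intervals plus the total read count
#' used for RPM/RPKM normalization. Scores are read densities in reads
#' per bp: integrating `score * bp` over a region gives the read count
#' attributed to it.
#'
#' @param intervals GRanges with a numeric `score` column, scores >= 0
#' @param total_reads total reads in the library (> 0 for normalized
#'   signal); default: the integral of the track
#' @return object of class `coverage_track`
#' @export
coverage_track <- function(intervals, total_reads = NULL) {
  if (is.null(intervals$score)) stop_config("coverage intervals need a score")
  if (any(intervals$score < 0)) stop_config("coverage scores must be >= 0")
  intervals <- GenomicRanges::sort(intervals, ignore.strand = TRUE)
  red <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(intervals)))
    stop_config("coverage intervals must be non-overlapping")
  total_reads <- total_reads %||%
    sum(intervals$score * GenomicRanges::width(intervals))
  structure(list(intervals = intervals, total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals, %.0f total reads\n",
              length(x$intervals), x$total_reads))
  invisible(x)
}

#' Build a coverage track from a set of reads
#'
#' Per-base read depth is computed with the run-length coverage of
#' GenomicRanges and divided by the read length, yielding densities in
#' reads per bp whose integral equals the number of reads.
#'
#' @param reads GRanges of read alignments (e.g. from a BED of reads)
#' @param read_length read length in bp used for the density scaling;
#'   default: the modal read width
#' @return a [coverage_track()] with `total_reads = length(reads)`
#' @export
coverage_from_reads <- function(reads, read_length = NULL) {
  if (is.null(read_length)) {
    w <- table(GenomicRanges::width(reads))
    read_length <- as.integer(names(w)[which.max(w)])
  }
  cov <- GenomicRanges::coverage(reads)
  gr <- GenomicRanges::GRanges(cov)
  gr <- gr[gr$score > 0]
  gr$score <- gr$score / read_length
  coverage_track(gr, total_reads = length(reads))
}

#' Quantify coverage signal over regions
#'
#' Raw signal of a region is the integral `sum(score * bp)` of the
#' track over it (a read count given density scores); `rpm` scales by
#' `1e6 / total_reads` and `rpkm` further by `1e3 / region length`.
#'
#' @param track a [coverage_track()]
#' @param regions GRanges
#' @param norm `"rpm"` (default), `"rpkm"` or `"raw"`
#' @return numeric vector, one value per region (0, with a warning,
#'   for regions on chromosomes absent from the track)
#' @export
region_signal <- function(track, regions, norm = c("rpm", "rpkm", "raw")) {
  norm <- match.arg(norm)
  stopifnot(inherits(track, "coverage_track"))
  if (norm != "raw" && track$total_reads <= 0)
    stop_config("total_reads must be > 0 for normalized signal")
  absent <- setdiff(as.character(unique(GenomicRanges::seqnames(regions))),
                    as.character(unique(GenomicRanges::seqnames(track$intervals))))
  if (length(absent))
    warning("region(s) on chromosome(s) absent from coverage track: ",
            paste(absent, collapse = ", "), call. = FALSE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(regions, track$intervals,
                                ignore.strand = TRUE))
  ri <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(regions)[ri],
             GenomicRanges::end(track$intervals)[ti]) -
    pmax(GenomicRanges::start(regions)[ri],
         GenomicRanges::start(track$intervals)[ti]) + 1L
  raw <- numeric(length(regions))
  if (length(ri)) {
    contrib <- track$intervals$score[ti] * ov
    agg <- rowsum(contrib, group = ri)
    raw[as.integer(rownames(agg))] <- agg[, 1]
  }
  switch(norm,
         raw = raw,
         rpm = raw * 1e6 / track$total_reads,
         rpkm = raw * 1e6 / track$total_reads * 1e3 /
           GenomicRanges::width(regions))
}

#' Summit-centered binned signal matrix
#'
#' For each peak, bins the coverage over the window
#' `[summit - flank, summit + flank)` into `n_bins` equal bins and
#' normalizes each bin (RPKM by default, using the nominal bin width).
#' Windows running past a chromosome end are zero-padded with a
#' warning. Optionally orders rows by average-linkage hierarchical
#' clustering of the matrix for heatmap display.
#'
#' @param track a [coverage_track()]
#' @param peaks GRanges with a 0-based `summit` offset column
#' @param flank half-window in bp (> 0); 5 kb reproduces the usual
#'   summit +/- 5 kb heatmap window
#' @param n_bins even number of bins (>= 1); `2 * flank` must be a
#'   multiple of `n_bins`
#' @param norm `"rpkm"` (default), `"rpm"` or `"raw"`
#' @param order_rows cluster-order the rows (hclust, average linkage,
#'   euclidean)?
#' @return matrix peaks x bins, with attribute `row_order`
#' @export
summit_matrix <- function(track, peaks, flank = 5000, n_bins = 100,
                          norm = c("rpkm", "rpm", "raw"),
                          order_rows = FALSE) {
  norm <- match.arg(norm)
  if (flank <= 0) stop_config("flank must be > 0")
  if (n_bins < 1 || n_bins %% 2 != 0)
    stop_config("n_bins must be a positive even count")
  if ((2 * flank) %% n_bins != 0)
    stop_config("2 * flank must be a multiple of n_bins")
  if (is.null(peaks$summit)) stop_config("peaks need a summit column")
  w <- (2 * flank) %/% n_bins
  summit0 <- GenomicRanges::start(peaks) - 1L + peaks$summit
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  # all bins of all peaks at once, 0-based
  bin_start0 <- rep(summit0 - flank, each = n_bins) +
    rep((seq_len(n_bins) - 1L) * w, times = length(peaks))
  bin_end0 <- bin_start0 + w
  sl <- GenomeInfoDb::seqlengths(peaks)[rep(chrom, each = n_bins)]
  clip_start <- pmax(bin_start0, 0)
  clip_end <- ifelse(is.na(sl), bin_end0, pmin(bin_end0, sl))
  clipped <- clip_start != bin_start0 | clip_end != bin_end0
  if (any(clipped))
    warning("summit window(s) exceed chromosome bounds; zero-padded",
            call. = FALSE)
  valid <- clip_start < clip_end
  raw <- numeric(length(bin_start0))
  if (any(valid)) {
    bins <- GenomicRanges::GRanges(
      rep(chrom, each = n_bins)[valid],
      IRanges::IRanges(start = clip_start[valid] + 1L, end = clip_end[valid]))
    raw[valid] <- region_signal(track, bins, norm = "raw")
  }
  vals <- switch(norm,
                 raw = raw,
                 rpm = raw * 1e6 / track$total_reads,
                 rpkm = raw * 1e6 / track$total_reads * 1e3 / w)
  m <- matrix(vals, nrow = length(peaks), ncol = n_bins, byrow = TRUE,
              dimnames = list(peaks$name %||%
                                sprintf("peak%03d", seq_along(peaks)),
                              sprintf("bin%03d", seq_len(n_bins))))
  row_order <- seq_len(nrow(m))
  if (order_rows && nrow(m) > 2)
    row_order <- stats::hclust(stats::dist(m), method = "average")$order
  m <- m[row_order, , drop = FALSE]
  attr(m, "row_order") <- row_order
  m
}

# ---- file I/O (BED / bedGraph / GFF), all 0-based half-open on disk ----

#' Read and write BED-family files
#'
#' Plain BED via rtracklayer; peak BED6+1 carries the 0-based summit
#' offset in column 7 (written directly, since standard BED has no
#' summit field). bedGraph stores coverage densities; `total_reads`
#' must be supplied on read if RPM-normalized signal is needed later
#' (default: the track integral).
#'
#' @param path file path
#' @param seqlengths optional named chromosome lengths
#' @return GRanges (`read_bed`, `read_gff_genes`), GRanges with a
#'   `summit` column (`read_peaks_bed`), or [coverage_track()]
#'   (`read_bedgraph`)
#' @export
read_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @rdname read_bed
#' @param gr GRanges to write
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @export
read_peaks_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(summit = "integer"))
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @rdname read_bed
#' @param peaks GRanges with `summit` column
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$name %||% sprintf("peak%03d", seq_along(peaks)),
    score = peaks$score %||% 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(peaks))),
    summit = peaks$summit)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @param total_reads library size for the resulting track
#' @export
read_bedgraph <- function(path, total_reads = NULL, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  coverage_track(gr, total_reads = total_reads)
}

#' @rdname read_bed
#' @param track a [coverage_track()]
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track$intervals, path, format = "bedGraph")
  invisible(path)
}

#' @rdname read_bed
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF")
  gr <- gr[gr$type == "gene"]
  gr$name <- gr$Name %||% gr$ID
  gr
}
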