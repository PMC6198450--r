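#' Tile a genome into fixed-width intervals
#'
#' Builds the coordinate frame used by all track statistics: non-overlapping,
#' half-open `[start, end)` intervals of at most `width` bp tiled per
#' chromosome, the terminal interval truncated at the chromosome end.
#' The default 10 kb width is the genomic resolution used throughout the
#' repeat-element correlation analyses.
#'
#' @param chrom_sizes named numeric vector or two-column data.frame
#'   (chromosome, length in bp).
#' @param width interval width in bp (default 10000).
#' @return An `interval_grid` object wrapping a [GenomicRanges::GRanges] of
#'   tiles (in input chromosome order), the chromosome sizes and the width.
#' @examples
#' g <- bin_genome(c(chrA = 25000), width = 10000)
#' length(g)  # 3 intervals: 0-10000, 10000-20000, 20000-25000
#' @export
bin_genome <- function(chrom_sizes, width = 10000L) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]),
                                   as.character(chrom_sizes[[1]]))
  }
  if (length(chrom_sizes) == 0L) stop("no chromosomes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named")
  if (any(chrom_sizes <= 0)) stop("all chromosome lengths must be > 0")
  if (length(width) != 1L || width <= 0) stop("width must be a single value > 0")
  width <- as.integer(width)

  sl <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  structure(
    list(ranges = tiles, chrom_sizes = sl, width = width),
    class = "interval_grid"
  )
}

#' @export
length.interval_grid <- function(x) length(x$ranges)

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("interval_grid: %d intervals of width %d bp over %d chromosome(s)\n",
              length(x), x$width, length(x$chrom_sizes)))
  invisible(x)
}

#' Interval boundaries of a grid as a 0-based half-open data.frame
#'
#' @param grid an `interval_grid`.
#' @return data.frame with columns chrom, start (0-based), end (exclusive).
#' @export
grid_intervals <- function(grid) {
  stopifnot(inherits(grid, "interval_grid"))
  r <- grid$ranges
  data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
             start = GenomicRanges::start(r) - 1L,
             end = GenomicRanges::end(r),
             stringsAsFactors = FALSE)
}

.grid_signature <- function(grid) {
  list(chrom_sizes = grid$chrom_sizes, width = grid$width)
}

.same_grid <- function(a, b) identical(.grid_signature(a), .grid_signature(b))

#' Construct a feature track on a grid
#'
#' One finite-or-missing numeric value per grid interval. Missing values are
#' `NA`, never silently zero; downstream correlations drop them pairwise.
#'
#' @param values numeric vector, one per interval (`NA` = missing).
#' @param grid the `interval_grid` the values live on.
#' @param label track label used in correlation matrices.
#' @return a `feature_track` object.
#' @export
feature_track <- function(values, grid, label = "track") {
  stopifnot(inherits(grid, "interval_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop("values length (", length(values), ") != number of intervals (",
         length(grid), ")")
  if (any(is.infinite(values))) stop("track values must be finite or NA")
  structure(list(label = label, values = values, grid = grid),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  v <- x$values
  cat(sprintf("feature_track '%s': %d intervals, %d missing, range [%s, %s]\n",
              x$label, length(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

# Coerce annotation input (data.frame with chrom/start/end 0-based half-open,
# or GRanges) to a GRanges carrying repeat_class/repeat_name metadata.
.as_annotation_gr <- function(annotations) {
  if (methods::is(annotations, "GRanges")) return(annotations)
  stopifnot(is.data.frame(annotations))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(annotations)))
    stop("annotation data.frame needs columns: ", paste(need, collapse = ", "))
  if (any(annotations$start >= annotations$end))
    stop("annotation start must be < end")
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = if ("strand" %in% names(annotations)) annotations$strand else "*"
  )
  for (col in c("repeat_class", "repeat_name"))
    if (col %in% names(annotations))
      S4Vectors::mcols(gr)[[col]] <- annotations[[col]]
  gr
}

#' Count repeat elements per interval (midpoint rule)
#'
#' Each annotation is assigned to exactly one interval — the one containing
#' its midpoint `floor((start + end) / 2)` under the half-open convention —
#' so boundary-spanning elements are never double counted and the track sums
#' to the number of annotations ("number of copies" semantics).
#'
#' @param grid an `interval_grid`.
#' @param annotations GRanges (1-based) or data.frame (`chrom`, `start`, `end`
#'   0-based half-open, optional `repeat_class`, `repeat_name`).
#' @param class_filter optional single repeat_class to count; `NULL` counts all.
#' @return `feature_track` of non-negative integer counts. Annotations on
#'   chromosomes absent from the grid are skipped with a warning; the skip
#'   count is attached as `attr(track, "n_skipped")`.
#' @export
count_elements <- function(grid, annotations, class_filter = NULL) {
  stopifnot(inherits(grid, "interval_grid"))
  gr <- .as_annotation_gr(annotations)
  label <- if (is.null(class_filter)) "count" else class_filter
  if (!is.null(class_filter)) {
    cls <- S4Vectors::mcols(gr)$repeat_class
    if (is.null(cls)) stop("class_filter given but annotations lack repeat_class")
    gr <- gr[!is.na(cls) & cls == class_filter]
  }

  on_grid <- as.character(GenomicRanges::seqnames(gr)) %in% names(grid$chrom_sizes)
  n_skipped <- sum(!on_grid)
  if (n_skipped > 0L) {
    warning(n_skipped, " annotation(s) on chromosomes absent from the grid; skipped")
    gr <- gr[on_grid]
  }

  counts <- integer(length(grid))
  if (length(gr) > 0L) {
    # midpoint in 0-based coords, looked up half-open
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    mid0 <- (start0 + end0) %/% 2L
    mid_gr <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr),
      ranges = IRanges::IRanges(start = mid0 + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(mid_gr, grid$ranges)
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  tr <- feature_track(counts, grid, label = label)
  attr(tr, "n_skipped") <- n_skipped
  tr
}

#' GC-content track
#'
#' Per-interval GC fraction `(G + C) / (A + C + G + T)`; intervals whose
#' sequence contains no unambiguous base (e.g., all N) are missing.
#'
#' @param grid an `interval_grid`.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return `feature_track` of GC fractions in `[0, 1]` (NA where undefined).
#' @export
gc_track <- function(grid, genome) {
  stopifnot(inherits(grid, "interval_grid"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- names(genome)
  # FASTA headers may carry descriptions after the id
  names(genome) <- sub("\\s.*$", "", nm)
  missing_chr <- setdiff(names(grid$chrom_sizes), names(genome))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) missing from FASTA: ", paste(missing_chr, collapse = ", "))

  iv <- grid_intervals(grid)
  values <- rep(NA_real_, length(grid))
  for (chr in names(grid$chrom_sizes)) {
    idx <- which(iv$chrom == chr)
    if (length(idx) == 0L) next
    sq <- genome[[chr]]
    if (length(sq) < grid$chrom_sizes[[chr]])
      stop("sequence for ", chr, " shorter than declared chromosome length")
    v <- Biostrings::Views(sq, start = iv$start[idx] + 1L, end = iv$end[idx])
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    values[idx] <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
  }
  feature_track(values, grid, label = "GC")
}

#' RPKM coverage track
#'
#' Reads per kilobase of interval per million mapped reads. Each read
#' placement is counted at its 5' position (a single point), so a placement
#' falls in exactly one interval; terminal partial intervals use their true
#' length. Multi-mapped reads contribute one count per placement here — the
#' metarepeat module applies its own disambiguation rule separately.
#'
#' @param grid an `interval_grid`.
#' @param reads data.frame with `chrom` and 0-based 5' position `pos`
#'   (e.g., from [read_sam_minimal()]), or a GRanges whose starts are used.
#' @param total_mapped_reads library size used for the per-million scaling.
#' @return `feature_track` of RPKM values.
#' @export
rpkm_track <- function(grid, reads, total_mapped_reads) {
  stopifnot(inherits(grid, "interval_grid"))
  if (length(total_mapped_reads) != 1L || total_mapped_reads <= 0)
    stop("total_mapped_reads must be a single value > 0")
  if (methods::is(reads, "GRanges")) {
    reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                        pos = GenomicRanges::start(reads) - 1L)
  }
  stopifnot(all(c("chrom", "pos") %in% names(reads)))

  len <- GenomicRanges::width(grid$ranges)
  if (any(len == 0L)) stop("zero-length interval in grid")

  counts <- integer(length(grid))
  keep <- reads$chrom %in% names(grid$chrom_sizes)
  if (any(keep)) {
    pt <- GenomicRanges::GRanges(
      seqnames = reads$chrom[keep],
      ranges = IRanges::IRanges(start = reads$pos[keep] + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(pt, grid$ranges)
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  rpkm <- counts / ((len / 1000) * (total_mapped_reads / 1e6))
  feature_track(rpkm, grid, label = "RPKM")
}
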