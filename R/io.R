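#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop("no chromosomes")
  stats::setNames(df$size, df$chrom)
}

#' Read repeat annotations from a BED file
#'
#' BED3/BED6; for repeat annotations the name column (4th) is taken as the
#' repeat class. Coordinates stay in BED's native 0-based half-open
#' convention in the returned data.frame.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end and, when present,
#'   repeat_class and strand columns.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$repeat_class <- as.character(df[[4]])
  if (ncol(df) >= 6L) out$strand <- as.character(df[[6]])
  out
}

#' Write repeat annotations to BED
#'
#' @param annotations data.frame with chrom, start, end (0-based half-open)
#'   and optional repeat_class (written as the name column) and strand.
#' @param path output path.
#' @export
write_bed <- function(annotations, path) {
  df <- annotations
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$repeat_class)) {
    cols <- c(cols, list(df$repeat_class, rep(0L, nrow(df)),
                         if (is.null(df$strand)) rep("+", nrow(df)) else df$strand))
  }
  utils::write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read RepeatMasker .out annotations
#'
#' Parses the standard RepeatMasker output table (3 header lines, whitespace-
#' separated fields). RepeatMasker coordinates are 1-based inclusive and are
#' converted to the package's internal 0-based half-open convention. The
#' class/family field is reduced to its class part (text before "/").
#'
#' @param path .out file path.
#' @return data.frame with chrom, start, end, strand, repeat_name,
#'   repeat_class.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  # drop header block (starts with "SW"/"score" columns) and blank lines
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(SW|score|bit)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), repeat_name = character(),
                      repeat_class = character(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, length, 1L) >= 11L
  fields <- fields[ok]
  get <- function(i) vapply(fields, `[[`, "", i)
  strand <- get(9)
  strand[strand == "C"] <- "-"
  data.frame(
    chrom = get(5),
    start = as.integer(get(6)) - 1L,   # 1-based inclusive -> 0-based half-open
    end = as.integer(get(7)),
    strand = strand,
    repeat_name = get(10),
    repeat_class = sub("/.*$", "", get(11)),
    stringsAsFactors = FALSE
  )
}

# reference-space width of a CIGAR string: sum of M/D/N/=/X operation lengths
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
}

#' Read a minimal SAM file
#'
#' Consumes the five mandatory fields used by the pipeline (QNAME, FLAG,
#' RNAME, POS, CIGAR); header lines are skipped and unmapped records
#' (FLAG 0x4 or RNAME "*") dropped. Multi-mapped reads may appear either as
#' repeated records sharing a QNAME or as XA-style auxiliary tags
#' (`XA:Z:chr,pos,cigar,nm;...`, strand sign on pos tolerated); both dialects
#' yield one placement row each.
#'
#' @param path SAM file path.
#' @return data.frame of placements: read_id, chrom, start, end
#'   (0-based half-open).
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, "", i)
  qname <- get(1); flag <- as.integer(get(2)); rname <- get(3)
  pos <- as.integer(get(4)); cigar <- get(6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  out <- data.frame(read_id = qname[mapped], chrom = rname[mapped],
                    start = pos[mapped] - 1L,
                    end = pos[mapped] - 1L + .cigar_ref_width(cigar[mapped]),
                    stringsAsFactors = FALSE)
  # XA-style alternative placements
  xa_rows <- lapply(which(mapped), function(i) {
    f <- fields[[i]]
    xa <- f[startsWith(f, "XA:Z:")]
    if (length(xa) == 0L) return(NULL)
    alts <- strsplit(sub("^XA:Z:", "", xa[1]), ";", fixed = TRUE)[[1]]
    alts <- alts[nzchar(alts)]
    parts <- strsplit(alts, ",", fixed = TRUE)
    p <- as.integer(sub("^[+-]", "", vapply(parts, `[[`, "", 2)))
    data.frame(read_id = f[1],
               chrom = vapply(parts, `[[`, "", 1),
               start = p - 1L,
               end = p - 1L + .cigar_ref_width(vapply(parts, `[[`, "", 3)),
               stringsAsFactors = FALSE)
  })
  xa_rows <- xa_rows[!vapply(xa_rows, is.null, TRUE)]
  if (length(xa_rows) > 0L) out <- rbind(out, do.call(rbind, xa_rows))
  rownames(out) <- NULL
  out
}

#' Write placements as a minimal SAM file
#'
#' Multi-placements are written as repeated records per QNAME (secondary
#' records carry FLAG 256). Reads are written as perfect matches of their
#' reference span (`<len>M`).
#'
#' @param placements data.frame: read_id, chrom, start, end (0-based
#'   half-open).
#' @param chrom_sizes named lengths for the @SQ header lines.
#' @param path output path.
#' @export
write_sam_minimal <- function(placements, chrom_sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  first <- !duplicated(placements$read_id)
  flag <- ifelse(first, 0L, 256L)
  len <- placements$end - placements$start
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                 placements$read_id, flag, placements$chrom,
                 placements$start + 1L, ifelse(first, 60L, 0L), len,
                 strrep("N", pmax(len, 1L)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a bedGraph track onto a grid
#'
#' Each bedGraph record contributes its value to the grid interval containing
#' its midpoint; intervals receiving no record are missing. Use for
#' pre-binned tracks (records matching grid intervals map one-to-one).
#'
#' @param grid an `interval_grid`.
#' @param path bedGraph file path.
#' @param label track label.
#' @return a `feature_track`.
#' @export
read_bedgraph_track <- function(grid, path, label = "bedgraph") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  df <- df[!grepl("^(track|browser)", df[[1]]), , drop = FALSE]
  values <- rep(NA_real_, length(grid))
  mid0 <- (as.integer(df[[2]]) + as.integer(df[[3]])) %/% 2L
  keep <- df[[1]] %in% names(grid$chrom_sizes)
  if (any(keep)) {
    pt <- GenomicRanges::GRanges(seqnames = df[[1]][keep],
                                 ranges = IRanges::IRanges(mid0[keep] + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(pt, grid$ranges)
    values[S4Vectors::subjectHits(hits)] <- as.numeric(df[[4]][keep])[S4Vectors::queryHits(hits)]
  }
  feature_track(values, grid, label = label)
}

#' Write a feature track as bedGraph
#'
#' Missing intervals are omitted from the output, preserving the distinction
#' between missing and zero.
#'
#' @param track a `feature_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  iv <- grid_intervals(track$grid)
  keep <- !is.na(track$values)
  utils::write.table(
    data.frame(iv$chrom[keep], iv$start[keep], iv$end[keep],
               track$values[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a set of tracks as a wide TSV
#'
#' One row per interval (chrom, start, end), one column per track, `NA` for
#' missing values.
#'
#' @param tracks list of `feature_track`s sharing one grid.
#' @param path output path.
#' @export
write_tracks_tsv <- function(tracks, path) {
  stopifnot(length(tracks) > 0L)
  grid <- tracks[[1]]$grid
  for (tr in tracks)
    if (!.same_grid(tr$grid, grid)) stop("tracks on different grids")
  df <- grid_intervals(grid)
  for (tr in tracks) df[[tr$label]] <- tr$values
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide track TSV back into feature tracks
#'
#' @param grid the `interval_grid` the file was written from.
#' @param path TSV path as written by [write_tracks_tsv()].
#' @return named list of `feature_track`s.
#' @export
read_tracks_tsv <- function(grid, path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  iv <- grid_intervals(grid)
  if (nrow(df) != nrow(iv) || !all(df$chrom == iv$chrom & df$start == iv$start))
    stop("TSV does not match grid")
  labs <- setdiff(names(df), c("chrom", "start", "end"))
  stats::setNames(lapply(labs, function(l) feature_track(df[[l]], grid, l)), labs)
}
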