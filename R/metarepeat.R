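#' Assign reads to repeat classes ("metarepetitive element" rule)
#'
#' Most reads originating from repetitive elements cannot be mapped uniquely
#' and are lost by unique-mappability filters. The metarepeat rule recovers
#' them: a read whose placements all fall in copies of one repeat class still
#' carries an unambiguous class signature and is counted into that class; a
#' read whose placements touch two or more distinct classes is discarded;
#' a read none of whose placements overlaps any annotated repeat is
#' non-repeat. Reads mixing repeat and non-repeat placements are discarded by
#' default (counted reads must carry the signature of a single repeat class
#' only); set `mixed_policy = "class"` to count them by their repeat class
#' instead.
#'
#' Any overlap of at least 1 bp between a placement and an annotation counts
#' as overlap with that annotation's class. A placement overlapping
#' annotations of two classes at once contributes both classes (and so
#' discards the read). Placements on chromosomes absent from the annotation
#' are treated as non-repeat overlaps.
#'
#' @param placements data.frame of read placements: `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open; from [read_sam_minimal()] or the
#'   read simulator).
#' @param annotations repeat annotations: GRanges or data.frame with a
#'   `repeat_class` column (see [count_elements()]).
#' @param grouping optional named character vector mapping annotation
#'   repeat_class values (e.g., RepeatMasker families) onto reported classes
#'   (e.g., `c(AluY = "Alu", L1PA2 = "LINE")`). Unlisted classes are kept
#'   verbatim.
#' @param mixed_policy `"discard"` (default) or `"class"`; see above.
#' @return character vector of one assignment per distinct read_id (names =
#'   read_id, in first-appearance order): a class name, `"NONREPEAT"` or
#'   `"DISCARD"`.
#' @export
classify_reads <- function(placements, annotations, grouping = NULL,
                           mixed_policy = c("discard", "class")) {
  mixed_policy <- match.arg(mixed_policy)
  stopifnot(all(c("read_id", "chrom", "start", "end") %in% names(placements)))
  ann <- .as_annotation_gr(annotations)
  cls <- S4Vectors::mcols(ann)$repeat_class
  if (is.null(cls)) stop("annotations lack repeat_class")
  cls <- as.character(cls)
  if (!is.null(grouping)) {
    mapped <- grouping[cls]
    cls <- ifelse(is.na(mapped), cls, mapped)
  }

  ids <- unique(placements$read_id)
  if (nrow(placements) == 0L)
    return(stats::setNames(character(0), character(0)))
  if (any(placements$start >= placements$end))
    stop("placement start must be < end")

  pl_gr <- GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$start + 1L,
                              end = placements$end))
  # placements on chromosomes unknown to the annotation simply get no hits,
  # i.e. count as non-repeat overlap
  suppressWarnings(hits <- GenomicRanges::findOverlaps(pl_gr, ann))
  qh <- S4Vectors::queryHits(hits)
  hit_class <- cls[S4Vectors::subjectHits(hits)]

  read_of_placement <- match(placements$read_id, ids)
  # distinct classes overlapped per read
  cls_per_read <- lapply(split(hit_class, read_of_placement[qh]), unique)
  n_classes <- integer(length(ids))
  one_class <- character(length(ids))
  idx <- as.integer(names(cls_per_read))
  n_classes[idx] <- lengths(cls_per_read)
  one_class[idx] <- vapply(cls_per_read, `[[`, "", 1L)
  # does the read have any placement with no repeat overlap at all?
  placement_hit <- tabulate(qh, nbins = nrow(placements)) > 0L
  has_nonrep_placement <- tapply(!placement_hit,
                                 factor(read_of_placement, levels = seq_along(ids)),
                                 any)
  has_nonrep_placement[is.na(has_nonrep_placement)] <- TRUE

  out <- character(length(ids))
  out[n_classes == 0L] <- "NONREPEAT"
  out[n_classes >= 2L] <- "DISCARD"
  single <- n_classes == 1L
  if (mixed_policy == "discard") {
    out[single & has_nonrep_placement] <- "DISCARD"
    out[single & !has_nonrep_placement] <- one_class[single & !has_nonrep_placement]
  } else {
    out[single] <- one_class[single]
  }
  stats::setNames(out, ids)
}

#' Classify a single read
#'
#' Convenience wrapper over [classify_reads()] for one `AlignedRead`.
#'
#' @param read list with `read_id` and `placements` (data.frame chrom, start,
#'   end), or a one-read placements data.frame.
#' @inheritParams classify_reads
#' @return single character assignment.
#' @export
classify_read <- function(read, annotations, grouping = NULL,
                          mixed_policy = c("discard", "class")) {
  if (is.data.frame(read)) {
    pl <- read
    if (is.null(pl$read_id)) pl$read_id <- "read"
  } else {
    pl <- read$placements
    pl$read_id <- read$read_id
  }
  unname(classify_reads(pl, annotations, grouping, mixed_policy)[1])
}

#' Tally classified reads into per-class counts
#'
#' @param assignments output of [classify_reads()].
#' @param timepoint label for the sample (e.g., "0.5h").
#' @return a `repeat_class_counts` object: per-class counts plus
#'   `n_nonrepeat`, `n_discarded` and `n_total`.
#' @export
count_repeat_classes <- function(assignments, timepoint = NA_character_) {
  is_special <- assignments %in% c("NONREPEAT", "DISCARD")
  counts <- table(factor(assignments[!is_special]))
  structure(list(timepoint = timepoint,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_nonrepeat = sum(assignments == "NONREPEAT"),
                 n_discarded = sum(assignments == "DISCARD"),
                 n_total = length(assignments)),
            class = "repeat_class_counts")
}

#' @export
print.repeat_class_counts <- function(x, ...) {
  cat(sprintf("repeat_class_counts [%s]: %d reads (%d non-repeat, %d discarded)\n",
              x$timepoint, x$n_total, x$n_nonrepeat, x$n_discarded))
  print(x$counts)
  invisible(x)
}

#' Per-class fractions of classified repeat reads
#'
#' Each class count is normalised to the total number of reads carrying a
#' single-class repeat signature; non-repeat and discarded reads never enter
#' the denominator. By default all counted classes form the denominator;
#' pass `classes` to restrict it to a reported subset (e.g., the four classes
#' Alu / LINE / SAT / LTR).
#'
#' @param class_counts a `repeat_class_counts`.
#' @param classes optional character vector restricting (and ordering) the
#'   denominator.
#' @return named numeric vector of fractions summing to 1.
#' @export
metarepeat_fractions <- function(class_counts, classes = NULL) {
  counts <- class_counts$counts
  if (!is.null(classes)) {
    counts <- stats::setNames(
      vapply(classes, function(cl) {
        if (cl %in% names(counts)) counts[[cl]] else 0L
      }, 0L), classes)
  }
  tot <- sum(counts)
  if (tot == 0L) stop("no classifiable reads")
  counts / tot
}

#' Relative enrichment of repeat classes against a baseline timepoint
#'
#' Ratio of class fractions at a timepoint over the corresponding fractions
#' at the baseline (e.g., unirradiated control). Fraction ratios are used
#' rather than raw-count ratios so the measure is invariant to library size.
#'
#' @param counts_t `repeat_class_counts` at the timepoint of interest.
#' @param counts_baseline `repeat_class_counts` at the baseline.
#' @param classes optional shared denominator restriction (see
#'   [metarepeat_fractions()]).
#' @return named numeric vector of ratios; classes with a zero baseline
#'   fraction are `NA` with a "zero_baseline" entry in
#'   `attr(, "reason")`.
#' @export
relative_enrichment <- function(counts_t, counts_baseline, classes = NULL) {
  if (is.null(classes))
    classes <- union(names(counts_baseline$counts), names(counts_t$counts))
  ft <- metarepeat_fractions(counts_t, classes)
  fb <- metarepeat_fractions(counts_baseline, classes)
  ratio <- ifelse(fb > 0, ft / fb, NA_real_)
  names(ratio) <- classes
  reason <- ifelse(fb > 0, NA_character_, "zero_baseline")
  names(reason) <- classes
  attr(ratio, "reason") <- reason
  ratio
}

#' Write per-timepoint metarepeat summary as TSV
#'
#' One row per class and timepoint: count, fraction, and enrichment relative
#' to the first (baseline) element of `counts_list`.
#'
#' @param counts_list list of `repeat_class_counts`, baseline first.
#' @param path output path.
#' @param classes optional denominator restriction.
#' @export
write_metarepeat_tsv <- function(counts_list, path, classes = NULL) {
  baseline <- counts_list[[1]]
  rows <- lapply(counts_list, function(cc) {
    fr <- metarepeat_fractions(cc, classes)
    en <- relative_enrichment(cc, baseline, classes = names(fr))
    data.frame(timepoint = cc$timepoint, class = names(fr),
               count = as.integer(cc$counts[names(fr)]),
               fraction = as.numeric(fr), enrichment = as.numeric(en),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$count[is.na(df$count)] <- 0L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
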