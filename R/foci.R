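# local maxima of a value array within a foreground mask (26-neighbourhood,
# >= comparison so plateaus qualify), followed by greedy suppression keeping
# maxima at least min_sep_um apart (strongest first; ties by linear index)
.seed_maxima <- function(value, fg, voxel_size, min_sep_um) {
  is_max <- fg
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    is_max <- is_max & (value >= .shift3(value, sx, sy, sz))
    if (!any(is_max)) return(integer(0))
  }
  cand <- which(is_max)
  if (length(cand) <= 1L) return(cand)
  ord <- order(-value[cand], cand)
  cand <- cand[ord]
  d <- dim(value)
  ijk <- arrayInd(cand, d)
  xyz <- sweep(ijk, 2, voxel_size, "*")
  kept <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (any(kept)) {
      dd <- sqrt(colSums((t(xyz[kept, , drop = FALSE]) - xyz[i, ])^2))
      if (min(dd) < min_sep_um) next
    }
    kept[i] <- TRUE
  }
  cand[kept]
}

# per-plane 3x3 binary median filter: a voxel stays foreground iff at least
# 5 of its 9 in-plane neighbours (zero-padded) are foreground. Planes are
# filtered independently because the axial voxel size is coarser than the
# lateral one; a cubic median would erode thin (2-3 plane) foci away.
.binary_median3 <- function(mask) {
  s <- array(0L, dim(mask))
  m <- mask * 1L
  for (sx in -1:1) for (sy in -1:1)
    s <- s + .shift3(m, sx, sy, 0L)
  s >= 5L
}

#' Segment repair foci within a nucleus
#'
#' Implements the focus-detection recipe used for gammaH2AX (and satellite)
#' regions: intensity threshold at the in-nucleus mean plus `k_sd` standard
#' deviations (the "SD" method, with `k_sd` calibrated once per condition),
#' fine-filter noise removal (per-plane 3x3 binary median), separation of touching
#' objects guided by a characteristic object size, removal of objects below
#' the minimum focus volume, and exclusion of objects not touching the
#' (dilated) nucleus.
#'
#' Touching-object separation is a seeded partition of each connected
#' component: seeds are local maxima of the component's depth map kept at
#' least `size_guide` um apart, and voxels join their nearest seed. For the
#' compact blob geometry of repair foci this coincides with the
#' distance-transform watershed.
#'
#' @param channel 3D focus-channel array.
#' @param nucleus `nucleus_mask` (its dilated labels gate inclusion) or
#'   logical array.
#' @param voxel_size `c(dx, dy, dz)` um (taken from `nucleus` if it is a
#'   `nucleus_mask`).
#' @param k_sd threshold stringency in SD units (default 3).
#' @param min_volume minimum focus volume in um^3 (default 0.3).
#' @param size_guide object size guide for separation, um (default 1).
#' @return a `foci_set`: label array `labels` and per-focus `table`
#'   (label, volume_um3, total_intensity), plus the threshold used. An empty
#'   set (e.g., unirradiated cells) is valid.
#' @export
segment_foci <- function(channel, nucleus, voxel_size = NULL, k_sd = 3,
                         min_volume = 0.3, size_guide = 1) {
  if (inherits(nucleus, "nucleus_mask")) {
    if (is.null(voxel_size)) voxel_size <- nucleus$voxel_size
    nuc <- .as_mask(nucleus)
    nuc_incl <- .as_mask(nucleus, dilated = TRUE)
  } else {
    nuc <- nucleus > 0
    nuc_incl <- nuc
  }
  if (is.null(voxel_size)) stop("voxel_size required")
  if (!any(nuc)) stop("empty nucleus mask")
  d <- dim(channel)
  empty <- function(thr) {
    structure(list(labels = array(0L, d),
                   table = data.frame(label = integer(), volume_um3 = numeric(),
                                      total_intensity = numeric()),
                   threshold = thr, voxel_size = voxel_size),
              class = "foci_set")
  }

  v <- channel[nuc]
  thr <- mean(v) + k_sd * stats::sd(v)
  fg <- channel > thr
  if (!any(fg)) return(empty(thr))
  fg <- .binary_median3(fg)
  if (!any(fg)) return(empty(thr))

  lab <- label_components_3d(fg)
  n0 <- max(lab)

  # split components carrying >= 2 depth-map seeds
  depth <- depth_map_um(fg, voxel_size)
  seeds <- .seed_maxima(depth, fg, voxel_size, size_guide)
  if (length(seeds) > 0L) {
    seed_comp <- lab[seeds]
    multi <- as.integer(names(which(table(seed_comp) >= 2L)))
    next_label <- n0
    for (comp in multi) {
      vox <- which(lab == comp)
      sc <- seeds[seed_comp == comp]
      vi <- sweep(arrayInd(vox, d), 2, voxel_size, "*")
      si <- sweep(arrayInd(sc, d), 2, voxel_size, "*")
      # nearest-seed assignment in physical coordinates
      d2 <- outer(rowSums(vi^2), rep(1, nrow(si))) -
        2 * vi %*% t(si) + outer(rep(1, nrow(vi)), rowSums(si^2))
      assign_to <- max.col(-d2, ties.method = "first")
      newlab <- c(comp, next_label + seq_len(nrow(si) - 1L))
      lab[vox] <- newlab[assign_to]
      next_label <- next_label + nrow(si) - 1L
    }
  }

  # volume filter and nucleus-inclusion test
  nlab <- max(lab)
  vv <- .voxel_volume(voxel_size)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  touches <- rep(FALSE, nlab)
  t_tab <- tapply(nuc_incl[lab > 0L], lab[lab > 0L], any)
  touches[as.integer(names(t_tab))] <- as.logical(t_tab)
  keep <- which(sizes * vv >= min_volume & touches)
  if (length(keep) == 0L) return(empty(thr))

  remap <- integer(nlab); remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  # renumber deterministically by first voxel position
  pos <- which(lab > 0L)
  first <- tapply(pos, lab[pos], min)
  ord <- order(first)
  remap2 <- integer(length(keep)); remap2[ord] <- seq_along(keep)
  lab[lab > 0L] <- remap2[lab[lab > 0L]]

  idx <- lab > 0L
  volume <- tabulate(lab[idx], nbins = length(keep)) * vv
  tot <- as.numeric(tapply(channel[idx], lab[idx], sum))
  structure(list(labels = lab,
                 table = data.frame(label = seq_along(keep),
                                    volume_um3 = volume,
                                    total_intensity = tot),
                 threshold = thr, voxel_size = voxel_size),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("foci_set: %d focus(i), threshold %.2f\n",
              nrow(x$table), x$threshold))
  invisible(x)
}

#' Fraction of a signal inside segmented regions
#'
#' Sum of the signal over region voxels divided by its sum over the whole
#' nucleus: the fraction-in-foci statistic (e.g., repeat-probe intensity
#' inside gammaH2AX foci over total nuclear probe intensity). The same
#' operation serves the reciprocal analysis, gammaH2AX fraction inside
#' segmented satellite regions.
#'
#' @param signal 3D array.
#' @param regions `foci_set`, label array or logical array.
#' @param nucleus `nucleus_mask` or logical array; both sums are restricted
#'   to the nucleus.
#' @return fraction in `[0, 1]`, or `NA` with `attr(, "reason")` when the
#'   nuclear signal is zero.
#' @export
fraction_in_regions <- function(signal, regions, nucleus) {
  if (inherits(regions, "foci_set")) regions <- regions$labels
  reg <- regions > 0
  nuc <- .as_mask(nucleus)
  denom <- sum(signal[nuc])
  if (denom <= 0) return(structure(NA_real_, reason = "zero_nuclear_signal"))
  sum(signal[nuc & reg]) / denom
}

#' Normalize repair-kinetics records to the 0.5-h median
#'
#' Adds a `fold_change` column: each cell's raw fraction divided by the
#' median raw fraction of the baseline (0.5 h) timepoint, so the baseline
#' median fold change is 1 by construction.
#'
#' @param records data.frame with columns `cell_id`, `timepoint` (hours) and
#'   `raw_fraction`.
#' @param baseline baseline timepoint (default 0.5).
#' @return `records` with `fold_change` added.
#' @export
normalize_kinetics <- function(records, baseline = 0.5) {
  stopifnot(all(c("cell_id", "timepoint", "raw_fraction") %in% names(records)))
  if (any(records$raw_fraction < 0 | records$raw_fraction > 1, na.rm = TRUE))
    stop("raw_fraction must lie in [0, 1]")
  base <- records$raw_fraction[records$timepoint == baseline &
                                 !is.na(records$raw_fraction)]
  if (length(base) == 0L)
    stop("no records at the baseline (", baseline, " h) timepoint")
  med <- stats::median(base)
  if (med <= 0) stop("baseline median fraction is not positive")
  records$fold_change <- records$raw_fraction / med
  records
}

#' Per-timepoint kinetics summary (box-plot statistics)
#'
#' Median, 2nd/3rd quartiles (linear-interpolation quantiles, R type 7) and
#' whisker fences at three times the interquartile distance beyond the
#' quartiles, per timepoint.
#'
#' @param records data.frame with `timepoint` and the summarised column.
#' @param value column to summarise (default `"fold_change"`).
#' @return data.frame: timepoint, n, median, q1, q3, whisker_low,
#'   whisker_high.
#' @export
summarize_kinetics <- function(records, value = "fold_change") {
  stopifnot(value %in% names(records))
  tps <- sort(unique(records$timepoint))
  rows <- lapply(tps, function(tp) {
    v <- records[[value]][records$timepoint == tp]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(timepoint = tp, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_low = q[1] - 3 * iqr, whisker_high = q[3] + 3 * iqr)
  })
  do.call(rbind, rows)
}
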