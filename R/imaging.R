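#' Construct a multichannel 3D image stack
#'
#' Channels are named 3D arrays indexed `[x, y, z]` sharing one shape, with
#' physical voxel sizes in micrometres. The reference acquisition geometry is
#' a lateral pixel size of 0.0866 um and a z-spacing of 0.125 um; synthetic
#' stacks may use coarser voxels.
#'
#' @param channels named list of non-negative 3D arrays (typical names:
#'   DNA, FISH, EdU, gH2AX).
#' @param voxel_size numeric `c(dx, dy, dz)` in um.
#' @return an `image_stack` object.
#' @export
image_stack <- function(channels, voxel_size = c(0.0866, 0.0866, 0.125)) {
  stopifnot(is.list(channels), length(channels) > 0L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  d <- dim(channels[[1]])
  if (length(d) != 3L) stop("channels must be 3D arrays")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!identical(dim(ch), d)) stop("channel '", nm, "' shape mismatch")
    if (any(ch < 0)) stop("channel '", nm, "' has negative intensities")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (dx, dy, dz) in um")
  structure(list(channels = channels, voxel_size = voxel_size, dim = d),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack %s: channels [%s], voxel %s um\n",
              paste(x$dim, collapse = "x"),
              paste(names(x$channels), collapse = ", "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

.voxel_volume <- function(voxel_size) prod(voxel_size)

# shift a 3D array by integer offsets, zero/FALSE padding
.shift3 <- function(a, sx = 0L, sy = 0L, sz = 0L) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- function(n, s) {
    i <- seq_len(n) - s
    ok <- i >= 1L & i <= n
    list(dst = seq_len(n)[ok], src = i[ok])
  }
  ix <- src(d[1], sx); iy <- src(d[2], sy); iz <- src(d[3], sz)
  out[ix$dst, iy$dst, iz$dst] <- a[ix$src, iy$src, iz$src]
  out
}

# 6-neighbourhood binary dilation / erosion, n iterations
.dilate6 <- function(mask, n = 1L) {
  for (i in seq_len(n)) {
    mask <- mask | .shift3(mask, 1) | .shift3(mask, -1) |
      .shift3(mask, 0, 1) | .shift3(mask, 0, -1) |
      .shift3(mask, 0, 0, 1) | .shift3(mask, 0, 0, -1)
  }
  mask
}

.erode6 <- function(mask, n = 1L) {
  for (i in seq_len(n)) {
    mask <- mask & .shift3(mask, 1) & .shift3(mask, -1) &
      .shift3(mask, 0, 1) & .shift3(mask, 0, -1) &
      .shift3(mask, 0, 0, 1) & .shift3(mask, 0, 0, -1)
  }
  mask
}

# per-plane hole filling (EBImage fillHull is 2D)
.fill_holes_planes <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[3]))
    out[, , z] <- EBImage::fillHull(mask[, , z] * 1L) > 0
  out
}

# 3D connected components (26-connectivity within plane via bwlabel's
# 8-connectivity, 6-connectivity across planes): per-plane bwlabel then
# union-find merge of labels overlapping between adjacent planes.
# Labels are deterministic: renumbered by the minimum linear voxel index.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    pl <- EBImage::bwlabel(mask[, , z] * 1L)
    pl <- as.integer(pl)
    pos <- pl > 0L
    pl[pos] <- pl[pos] + offset
    offset <- offset + max(0L, suppressWarnings(max(pl)))
    lab[, , z] <- pl
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_len(d[3] - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(offset), find, 0L)
  lab[lab > 0L] <- root[lab[lab > 0L]]
  # deterministic renumbering by first (minimum) linear index
  pos <- which(lab > 0L)
  first <- tapply(pos, lab[pos], min)
  old <- as.integer(names(sort(first)))
  remap <- integer(max(old))
  remap[old] <- seq_along(old)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# global Otsu threshold on the pooled intensity histogram
.otsu_global <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(Inf)
  EBImage::otsu(EBImage::Image(matrix(as.numeric(x), nrow = dim(x)[1])),
                range = rng, levels = levels)
}

# depth map: distance (um) from each in-mask voxel to the nearest outside
# voxel, as min(per-plane 2D EDT * dx, along-z run distance * dz). A
# conservative lower bound on the anisotropic 3D EDT, adequate for shell /
# interior partitions of smooth nuclear shapes.
depth_map_um <- function(mask, voxel_size) {
  d <- dim(mask)
  xy <- EBImage::distmap(mask * 1L)  # per-plane 2D EDT in pixels
  dz_planes <- array(0, d)
  up <- matrix(0, d[1], d[2]); down <- matrix(0, d[1], d[2])
  updist <- array(0, d); downdist <- array(0, d)
  for (z in seq_len(d[3])) {
    up <- ifelse(mask[, , z], up + 1, 0)
    updist[, , z] <- up
  }
  for (z in rev(seq_len(d[3]))) {
    down <- ifelse(mask[, , z], down + 1, 0)
    downdist[, , z] <- down
  }
  zrun <- pmin(updist, downdist)  # distance to nearest out-of-mask plane
  pmin(xy * voxel_size[1], zrun * voxel_size[3]) * (mask > 0)
}

.as_mask <- function(mask, dilated = FALSE) {
  if (inherits(mask, "nucleus_mask"))
    return((if (dilated) mask$labels_dilated else mask$labels) > 0L)
  mask > 0
}

#' Segment nuclei from the DNA counterstain channel
#'
#' Pipeline: per-plane Gaussian smoothing (sigma 1 px), global automatic
#' (Otsu) threshold, hole filling, removal of regions below the minimum
#' nuclear volume, then a 2-iteration dilation with a second hole fill to
#' produce the padded mask used for focus-inclusion tests. Region volumes
#' and integrated DNA intensities are measured on the segmented nucleus
#' proper (before dilation), so they estimate the true nuclear geometry; the
#' dilated labels are carried alongside.
#'
#' @param dna 3D DNA-channel array (or an `image_stack` with a DNA channel).
#' @param voxel_size `c(dx, dy, dz)` um (taken from the stack if given one).
#' @param min_volume minimum nuclear volume in um^3 (default 400).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param dilate_iter dilation iterations for the padded mask.
#' @return a `nucleus_mask`: label array `labels`, padded `labels_dilated`,
#'   and a per-region `table` (label, volume_um3, dna_total). Labels are
#'   ordered deterministically by position. If nothing survives, the mask is
#'   empty with a warning.
#' @export
nuclear_mask <- function(dna, voxel_size = NULL, min_volume = 400,
                         sigma = 1, dilate_iter = 2L) {
  if (inherits(dna, "image_stack")) {
    voxel_size <- dna$voxel_size
    dna <- dna$channels$DNA
    if (is.null(dna)) stop("stack has no DNA channel")
  }
  if (is.null(voxel_size)) stop("voxel_size required")
  d <- dim(dna)
  empty <- function() {
    warning("no nuclear region detected")
    structure(list(labels = array(0L, d), labels_dilated = array(0L, d),
                   table = data.frame(label = integer(), volume_um3 = numeric(),
                                      dna_total = numeric()),
                   voxel_size = voxel_size),
              class = "nucleus_mask")
  }
  if (diff(range(dna)) == 0) return(empty())

  sm <- EBImage::gblur(dna, sigma = sigma)
  thr <- .otsu_global(sm)
  bin <- sm > thr
  if (!any(bin)) return(empty())
  bin <- .fill_holes_planes(bin)
  lab <- label_components_3d(bin)
  vv <- .voxel_volume(voxel_size)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * vv >= min_volume)
  if (length(keep) == 0L) return(empty())
  remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]

  # label-preserving dilation (contested voxels resolved by fixed shift
  # order), then per-label per-plane hole fill
  dil <- lab
  for (i in seq_len(dilate_iter)) {
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- .shift3(dil, sh[1], sh[2], sh[3])
      grow <- dil == 0L & nb > 0L
      dil[grow] <- nb[grow]
    }
  }
  for (l in seq_along(keep)) {
    filled <- .fill_holes_planes(dil == l)
    dil[filled & dil == 0L] <- l
  }

  idx <- lab > 0L
  volume <- tabulate(lab[idx], nbins = length(keep)) * vv
  dna_total <- as.numeric(tapply(dna[idx], lab[idx], sum))
  structure(list(labels = lab, labels_dilated = dil,
                 table = data.frame(label = seq_along(keep),
                                    volume_um3 = volume,
                                    dna_total = dna_total),
                 voxel_size = voxel_size),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("nucleus_mask: %d region(s)\n", nrow(x$table)))
  if (nrow(x$table) > 0) print(x$table)
  invisible(x)
}

#' Local-mean background subtraction
#'
#' Subtracts, per z-plane, the mean intensity in a square
#' `(2 * radius_px + 1)^2` window around each pixel and clips at zero. This
#' removes smooth background (uneven illumination, diffuse signal) while
#' retaining structures smaller than the window, such as foci. When a mask
#' is given, the window mean is computed over in-mask pixels only, which
#' avoids the rim artifact of averaging dark out-of-mask pixels into the
#' background estimate near the nuclear boundary.
#'
#' @param channel 3D array.
#' @param radius_px window radius in pixels (default 10, about 0.87 um at
#'   the reference lateral pixel size).
#' @param mask optional `nucleus_mask` or logical array restricting the
#'   window mean.
#' @return background-subtracted array of the same shape.
#' @export
local_mean_subtract <- function(channel, radius_px = 10L, mask = NULL) {
  if (radius_px < 1L) stop("radius_px must be >= 1")
  k <- 2L * as.integer(radius_px) + 1L
  kern <- matrix(1, k, k)
  if (is.null(mask)) {
    bg <- EBImage::filter2(channel, kern / (k * k), boundary = "replicate")
  } else {
    m <- .as_mask(mask) * 1
    num <- EBImage::filter2(channel * m, kern, boundary = 0)
    den <- EBImage::filter2(m, kern, boundary = 0)
    bg <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
  }
  array(pmax(as.numeric(channel) - as.numeric(bg), 0), dim(channel))
}

#' Subtract the camera-offset background estimated outside the nucleus
#'
#' Estimates the constant background as the mean intensity of voxels outside
#' the (dilated) nuclear mask and subtracts it, clipping at zero. Unlike
#' [local_mean_subtract()], this preserves diffuse nuclear signal — which
#' must stay in the denominator of intensity-fraction measurements — and
#' removes only the flat offset.
#'
#' @param channel 3D array.
#' @param nucleus `nucleus_mask` or logical array.
#' @return background-subtracted array; the estimated offset is attached as
#'   `attr(, "offset")`.
#' @export
subtract_offset <- function(channel, nucleus) {
  m <- .as_mask(nucleus, dilated = TRUE)
  out_vox <- channel[!m]
  offset <- if (length(out_vox) > 0L) mean(out_vox) else 0
  res <- array(pmax(channel - offset, 0), dim(channel))
  attr(res, "offset") <- offset
  res
}

.plane_vectors <- function(ch1, ch2, mask, plane) {
  m <- .as_mask(mask)
  d <- dim(ch1)
  stopifnot(identical(dim(ch2), d), identical(dim(m), d),
            plane >= 1L, plane <= d[3])
  mp <- m[, , plane]
  list(v1 = ch1[, , plane][mp], v2 = ch2[, , plane][mp])
}

#' Per-plane Pearson colocalization coefficient
#'
#' Product-moment correlation of two channels over the in-mask pixels of one
#' z-plane; -1 is mutual exclusion, +1 perfect colocalization.
#'
#' @param ch1,ch2 3D channel arrays (background-subtracted upstream).
#' @param mask `nucleus_mask` or logical/label array; pixels outside are
#'   ignored.
#' @param plane z-plane index.
#' @return correlation in `[-1, 1]`, or `NA` with `attr(, "reason")` for
#'   degenerate planes (fewer than 3 in-mask pixels, constant channel).
#' @export
pearson_coloc <- function(ch1, ch2, mask, plane) {
  v <- .plane_vectors(ch1, ch2, mask, plane)
  if (length(v$v1) < 3L)
    return(structure(NA_real_, reason = "too_few_voxels"))
  if (stats::sd(v$v1) == 0 || stats::sd(v$v2) == 0)
    return(structure(NA_real_, reason = "constant_channel"))
  stats::cor(v$v1, v$v2)
}

#' Per-plane H colocalization coefficient
#'
#' Normalised intensity cross-product over the in-mask pixels of a plane:
#' `H = mean(ch1 * ch2) / (mean(ch1) * mean(ch2))`. For independent signals
#' the expectation is 1; co-enriched signals give H > 1, mutually exclusive
#' signals H < 1 (0 for disjoint supports). H is invariant to positive
#' rescaling of either channel.
#'
#' @inheritParams pearson_coloc
#' @return H >= 0, or `NA` with `attr(, "reason")` if either plane mean is
#'   not positive.
#' @export
h_coefficient <- function(ch1, ch2, mask, plane) {
  v <- .plane_vectors(ch1, ch2, mask, plane)
  if (length(v$v1) == 0L)
    return(structure(NA_real_, reason = "too_few_voxels"))
  m1 <- mean(v$v1); m2 <- mean(v$v2)
  if (m1 <= 0 || m2 <= 0)
    return(structure(NA_real_, reason = "zero_mean"))
  mean(v$v1 * v$v2) / (m1 * m2)
}

#' Select the mid-nuclear reporting plane
#'
#' The plane with the highest total in-mask DNA intensity, a proxy for the
#' best-signal mid-nuclear section; ties break to the lower index.
#'
#' @param dna 3D DNA-channel array.
#' @param mask `nucleus_mask` or logical array.
#' @return z-plane index.
#' @export
select_midplane <- function(dna, mask) {
  m <- .as_mask(mask)
  tot <- vapply(seq_len(dim(dna)[3]),
                function(z) sum(dna[, , z][m[, , z]]), 0)
  which.max(tot)  # ties -> first (lower index)
}

#' Colocalization profile of two channels across a nucleus
#'
#' Applies background subtraction to both channels, computes Pearson r and
#' the H coefficient for every z-plane with in-mask pixels, and reports the
#' mid-nuclear plane selected from the DNA channel.
#'
#' @param stack an `image_stack` containing `ch1`, `ch2` and a DNA channel.
#' @param ch1,ch2 channel names to correlate.
#' @param nucleus optional precomputed `nucleus_mask`; segmented from the
#'   DNA channel if omitted.
#' @param radius_px background-subtraction window radius
#'   ([local_mean_subtract()]); `NULL` skips subtraction.
#' @param min_volume passed to [nuclear_mask()] when segmenting.
#' @return a `coloc_result`: data.frame `per_plane` (plane, n_voxels, r, H),
#'   `midplane`, `midplane_r`, `midplane_h`.
#' @export
coloc_profile <- function(stack, ch1 = "FISH", ch2 = "EdU", nucleus = NULL,
                          radius_px = 10L, min_volume = 400) {
  stopifnot(inherits(stack, "image_stack"))
  for (nm in c(ch1, ch2, "DNA"))
    if (is.null(stack$channels[[nm]])) stop("stack lacks channel '", nm, "'")
  if (is.null(nucleus))
    nucleus <- nuclear_mask(stack$channels$DNA, stack$voxel_size,
                            min_volume = min_volume)
  m <- .as_mask(nucleus)
  a <- stack$channels[[ch1]]; b <- stack$channels[[ch2]]
  if (!is.null(radius_px)) {
    a <- local_mean_subtract(a, radius_px, mask = m)
    b <- local_mean_subtract(b, radius_px, mask = m)
  }
  nz <- dim(a)[3]
  nvox <- vapply(seq_len(nz), function(z) sum(m[, , z]), 0L)
  res <- data.frame(plane = seq_len(nz), n_voxels = nvox,
                    r = NA_real_, H = NA_real_)
  for (z in which(nvox > 0L)) {
    res$r[z] <- as.numeric(pearson_coloc(a, b, m, z))
    res$H[z] <- as.numeric(h_coefficient(a, b, m, z))
  }
  mid <- select_midplane(stack$channels$DNA, nucleus)
  structure(list(per_plane = res, midplane = mid,
                 midplane_r = res$r[mid], midplane_h = res$H[mid]),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result: midplane %d, r = %.3f, H = %.3f (%d planes)\n",
              x$midplane, x$midplane_r, x$midplane_h, nrow(x$per_plane)))
  invisible(x)
}
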