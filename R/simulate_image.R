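#' Specification for one synthetic nucleus image
#'
#' Describes a 3D multichannel acquisition of a single ellipsoidal nucleus
#' with planted ground truth: an EdU replication pattern (early: many small
#' interior foci; mid: rim-concentrated foci; late: few large distinct
#' spots; non-S: no EdU), a FISH channel either mixed against a reference at
#' a controlled colocalization level (`coloc_alpha`) or distributed with a
#' controlled fraction inside the gammaH2AX foci (`overlap_fraction`), and a
#' gammaH2AX channel of planted Gaussian foci. Channels receive Poisson
#' noise on top of a constant camera offset.
#'
#' @param semi_axes nucleus ellipsoid semi-axes `c(ax, ay, az)` in um.
#' @param voxel_size voxel size `c(dx, dy, dz)` in um. Synthetic stacks use
#'   0.25 x 0.25 x 0.4 um by default (coarser than the reference
#'   acquisition, keeping stacks small while leaving foci several voxels
#'   wide).
#' @param margin_um padding around the nucleus, um.
#' @param pattern EdU pattern: "early", "mid", "late" or "non-S".
#' @param coloc_alpha mixing weight of the FISH channel against the clean
#'   EdU reference (`NA` disables; 0 = independent, 1 = identical pattern).
#' @param overlap_fraction planted fraction of total nuclear FISH intensity
#'   inside the gammaH2AX focus regions (`NA` disables).
#' @param n_foci number of gammaH2AX foci.
#' @param foci_min_sep_um minimum distance between gammaH2AX focus centers
#'   (um); repair foci are spatially distinct objects.
#' @param focus_sigma_um Gaussian sigma of gammaH2AX foci `c(sx, sy, sz)` um.
#' @param focus_peak peak intensity of gammaH2AX foci (counts).
#' @param edu_peak peak intensity of EdU foci.
#' @param fish_total total clean FISH intensity distributed when planting
#'   `overlap_fraction`.
#' @param dna_level mean DNA-channel intensity inside the nucleus.
#' @param background constant offset (counts) added to every channel.
#' @param noise apply Poisson noise (TRUE) or return clean intensities.
#' @param seed integer seed.
#' @return an `image_sim_spec` list.
#' @export
image_sim_spec <- function(semi_axes = c(6, 6, 3.5),
                           voxel_size = c(0.25, 0.25, 0.4),
                           margin_um = 1,
                           pattern = c("early", "mid", "late", "non-S"),
                           coloc_alpha = NA_real_,
                           overlap_fraction = NA_real_,
                           n_foci = 15L,
                           foci_min_sep_um = 2,
                           focus_sigma_um = c(0.4, 0.4, 0.45),
                           focus_peak = 1500,
                           edu_peak = 2000,
                           fish_total = 2e6,
                           dna_level = 300,
                           background = 10,
                           noise = TRUE,
                           seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(all(semi_axes > 0), all(voxel_size > 0), margin_um >= 0,
            is.na(coloc_alpha) || (coloc_alpha >= 0 && coloc_alpha <= 1),
            is.na(overlap_fraction) ||
              (overlap_fraction >= 0 && overlap_fraction <= 1))
  structure(as.list(environment()), class = "image_sim_spec")
}

# add Gaussian blobs at physical centers (k x 3 matrix, um) onto a canvas;
# each blob is evaluated on a +-3 sigma bounding box only
.add_gaussian_foci <- function(canvas, centers, sigma_um, peak, voxel_size) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  d <- dim(canvas)
  for (k in seq_len(nrow(centers))) {
    ctr <- centers[k, ]
    ijk0 <- pmax(1L, floor((ctr - 3 * sigma_um) / voxel_size) + 1L)
    ijk1 <- pmin(d, ceiling((ctr + 3 * sigma_um) / voxel_size) + 1L)
    if (any(ijk0 > ijk1)) next
    xi <- (seq(ijk0[1], ijk1[1]) - 0.5) * voxel_size[1]
    yi <- (seq(ijk0[2], ijk1[2]) - 0.5) * voxel_size[2]
    zi <- (seq(ijk0[3], ijk1[3]) - 0.5) * voxel_size[3]
    gx <- exp(-((xi - ctr[1])^2) / (2 * sigma_um[1]^2))
    gy <- exp(-((yi - ctr[2])^2) / (2 * sigma_um[2]^2))
    gz <- exp(-((zi - ctr[3])^2) / (2 * sigma_um[3]^2))
    blob <- peak * outer(outer(gx, gy), gz)
    sl <- list(seq(ijk0[1], ijk1[1]), seq(ijk0[2], ijk1[2]),
               seq(ijk0[3], ijk1[3]))
    canvas[sl[[1]], sl[[2]], sl[[3]]] <-
      canvas[sl[[1]], sl[[2]], sl[[3]]] + blob
  }
  canvas
}

# sample n focus centers (physical um coords) from the voxels of a region;
# with min_sep_um > 0, rejection-sample so centers stay that far apart
# (distinct foci, as repair foci are)
.sample_centers <- function(region, n, voxel_size, min_sep_um = 0) {
  idx <- which(region)
  if (length(idx) == 0L) stop("empty sampling region")
  draw_one <- function() {
    pick <- idx[sample.int(length(idx), 1L)]
    ijk <- arrayInd(pick, dim(region))
    (ijk - 0.5 + stats::runif(3, -0.5, 0.5)) * voxel_size
  }
  if (min_sep_um <= 0) {
    pick <- idx[sample.int(length(idx), n, replace = length(idx) < n)]
    ijk <- arrayInd(pick, dim(region))
    jit <- matrix(stats::runif(n * 3, -0.5, 0.5), n, 3)
    return(sweep(ijk - 0.5 + jit, 2, voxel_size, "*"))
  }
  out <- matrix(NA_real_, n, 3)
  k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("cannot place ", n, " centers ", min_sep_um, " um apart")
    ctr <- as.numeric(draw_one())
    if (k > 0L) {
      dd <- sqrt(colSums((t(out[seq_len(k), , drop = FALSE]) - ctr)^2))
      if (min(dd) < min_sep_um) next
    }
    k <- k + 1L
    out[k, ] <- ctr
  }
  out
}

.edu_pattern <- function(spec, nucleus, depth, voxel_size) {
  canvas <- array(0, dim(nucleus))
  sig <- c(0.2, 0.2, 0.25)
  switch(spec$pattern,
    "non-S" = canvas,
    early = {
      ctr <- .sample_centers(nucleus & depth > 1.2, 120L, voxel_size)
      .add_gaussian_foci(canvas, ctr, sig, spec$edu_peak, voxel_size)
    },
    mid = {
      ctr <- .sample_centers(nucleus & depth > 0 & depth <= 0.8, 100L,
                             voxel_size)
      .add_gaussian_foci(canvas, ctr, sig, spec$edu_peak, voxel_size)
    },
    late = {
      ctr <- .sample_centers(nucleus & depth > 0.8, 8L, voxel_size)
      .add_gaussian_foci(canvas, ctr, c(0.5, 0.5, 0.5),
                         spec$edu_peak * 1.2, voxel_size)
    })
}

#' Simulate one multichannel 3D nucleus with ground truth
#'
#' Renders the acquisition described by an [image_sim_spec()]: DNA
#' counterstain (ellipsoid body with smooth texture), EdU replication
#' pattern, gammaH2AX foci, and a FISH channel at the requested
#' colocalization or focus-overlap level; Poisson noise and a constant
#' offset are applied last. Identical spec and seed give bit-identical
#' output.
#'
#' @param spec an `image_sim_spec`.
#' @return list with `stack` (an [image_stack()] with channels DNA, EdU,
#'   FISH, gH2AX) and `truth` (nucleus mask, gammaH2AX focus label array
#'   and centers, pattern label, planted coloc_alpha / overlap_fraction).
#' @export
simulate_image <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  vs <- spec$voxel_size
  half <- spec$semi_axes + spec$margin_um
  d <- as.integer(2 * ceiling(half / vs) + 1L)
  set.seed(spec$seed)

  ctr_um <- (d / 2) * vs
  x <- ((seq_len(d[1]) - 0.5) * vs[1] - ctr_um[1]) / spec$semi_axes[1]
  y <- ((seq_len(d[2]) - 0.5) * vs[2] - ctr_um[2]) / spec$semi_axes[2]
  z <- ((seq_len(d[3]) - 0.5) * vs[3] - ctr_um[3]) / spec$semi_axes[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  nucleus <- array(r2 <= 1, d)
  depth <- depth_map_um(nucleus, vs)

  # DNA: nucleus body with smooth multiplicative texture
  tex <- EBImage::gblur(array(stats::rnorm(prod(d)), d), sigma = 2)
  tex <- (tex - min(tex)) / max(diff(range(tex)), 1e-12)
  dna <- spec$dna_level * (0.85 + 0.3 * tex) * nucleus

  edu <- .edu_pattern(spec, nucleus, depth, vs)

  # gammaH2AX foci with a truth label array (nearest-center ellipsoidal
  # support at 2 sigma)
  gh <- array(0, d)
  foci_labels <- array(0L, d)
  centers <- NULL
  if (spec$n_foci > 0L) {
    centers <- .sample_centers(nucleus & depth > 0.5, spec$n_foci, vs,
                               min_sep_um = spec$foci_min_sep_um)
    gh <- .add_gaussian_foci(gh, centers, spec$focus_sigma_um,
                             spec$focus_peak, vs)
    pos_um <- cbind((slice.index(gh, 1) - 0.5) * vs[1],
                    (slice.index(gh, 2) - 0.5) * vs[2],
                    (slice.index(gh, 3) - 0.5) * vs[3])
    d2min <- array(Inf, d); nearest <- array(0L, d)
    for (k in seq_len(nrow(centers))) {
      d2 <- array((pos_um[, 1] - centers[k, 1])^2 / spec$focus_sigma_um[1]^2 +
                    (pos_um[, 2] - centers[k, 2])^2 / spec$focus_sigma_um[2]^2 +
                    (pos_um[, 3] - centers[k, 3])^2 / spec$focus_sigma_um[3]^2,
                  d)
      upd <- d2 < d2min
      d2min[upd] <- d2[upd]; nearest[upd] <- k
    }
    foci_labels[d2min <= 4] <- nearest[d2min <= 4]  # within 2 sigma
    foci_core <- d2min <= 1                          # within 1 sigma
  } else foci_core <- array(FALSE, d)

  # FISH channel: when planting an overlap fraction, the in-focus share is
  # confined to the 1-sigma focus cores (damage-site probe signal is
  # concentrated), so any reasonable focus segmentation captures it in full
  # and the planted fraction is recoverable
  if (!is.na(spec$overlap_fraction)) {
    f <- spec$overlap_fraction
    inside <- foci_core & nucleus
    outside <- nucleus & foci_labels == 0L
    fish <- array(0, d)
    if (sum(inside) > 0L) fish[inside] <- f * spec$fish_total / sum(inside)
    if (sum(outside) > 0L)
      fish[outside] <- (1 - f) * spec$fish_total / sum(outside)
  } else if (!is.na(spec$coloc_alpha)) {
    ref <- edu
    # independent component: many small foci with centers uniform over the
    # nucleus, so its mean field carries no shared large-scale structure
    # with the replication pattern (alpha = 0 is voxel-level independent,
    # E[H] = 1) yet it is fine-grained enough to survive local-mean
    # background subtraction
    ctr_i <- .sample_centers(nucleus & depth > 0.2, 250L, vs)
    indep <- .add_gaussian_foci(array(0, d), ctr_i, c(0.15, 0.15, 0.2),
                                spec$edu_peak / 2, vs)
    if (sum(indep) > 0 && sum(ref) > 0)
      indep <- indep * sum(ref) / sum(indep)
    fish <- spec$coloc_alpha * ref + (1 - spec$coloc_alpha) * indep
  } else {
    fish <- array(0, d)
    fish[nucleus] <- spec$fish_total / sum(nucleus)
  }

  noisy <- function(ch, sub) {
    lam <- ch + spec$background
    if (!spec$noise) return(lam)
    set.seed(.subseed(spec$seed, sub))
    array(stats::rpois(length(lam), lam), d)
  }
  stack <- image_stack(list(DNA = noisy(dna, 1L), EdU = noisy(edu, 2L),
                            FISH = noisy(fish, 3L), gH2AX = noisy(gh, 4L)),
                       voxel_size = vs)
  list(stack = stack,
       truth = list(nucleus = nucleus, foci_labels = foci_labels,
                    foci_centers = centers, pattern = spec$pattern,
                    coloc_alpha = spec$coloc_alpha,
                    overlap_fraction = spec$overlap_fraction))
}

#' Simulate a repair time course of nuclei with decaying focus overlap
#'
#' Emulates the irradiation experiment: cohorts of cells fixed at 0.5, 3 and
#' 24 h post-irradiation, in which the fraction of repeat-probe (FISH)
#' signal inside gammaH2AX foci decays over time. Each cell's planted
#' overlap is the baseline overlap times the timepoint's relative decay
#' times a small lognormal cell-to-cell factor. Cells are realised lazily
#' through `make_cell()` so a full cohort never needs to sit in memory.
#'
#' @param n_cells cells per timepoint (default 30).
#' @param timepoints hours post-irradiation (default 0.5, 3, 24).
#' @param decay relative overlap decay at each timepoint (default 1, 0.5,
#'   0.2, the first element being the 0.5-h reference).
#' @param base_overlap planted overlap fraction at the reference timepoint.
#' @param cell_sd lognormal sigma of cell-to-cell variability.
#' @param seed integer seed.
#' @param spec_args named list of overrides passed to [image_sim_spec()]
#'   for every cell.
#' @return list with `manifest` (data.frame: index, cell_id, timepoint,
#'   overlap_truth, seed) and `make_cell(index)` realising the
#'   [simulate_image()] output for one row.
#' @export
simulate_repair_timecourse <- function(n_cells = 30L,
                                       timepoints = c(0.5, 3, 24),
                                       decay = c(1, 0.5, 0.2),
                                       base_overlap = 0.4,
                                       cell_sd = 0.12,
                                       seed = 1L,
                                       spec_args = list()) {
  stopifnot(length(decay) == length(timepoints), length(timepoints) >= 1L)
  set.seed(seed)
  manifest <- do.call(rbind, lapply(seq_along(timepoints), function(i) {
    data.frame(timepoint = timepoints[i], rel_decay = decay[i],
               cell = seq_len(n_cells))
  }))
  manifest$index <- seq_len(nrow(manifest))
  manifest$cell_id <- sprintf("t%g_cell%02d", manifest$timepoint,
                              manifest$cell)
  jitter <- exp(stats::rnorm(nrow(manifest), 0, cell_sd))
  manifest$overlap_truth <- pmin(pmax(base_overlap * manifest$rel_decay *
                                        jitter, 0.01), 0.9)
  manifest$seed <- vapply(manifest$index, function(i) .subseed(seed, 100L + i), 0L)
  manifest <- manifest[, c("index", "cell_id", "timepoint", "rel_decay",
                           "overlap_truth", "seed")]
  make_cell <- function(index) {
    row <- manifest[manifest$index == index, ]
    stopifnot(nrow(row) == 1L)
    args <- utils::modifyList(
      list(pattern = "non-S", overlap_fraction = row$overlap_truth,
           seed = row$seed),
      spec_args)
    simulate_image(do.call(image_sim_spec, args))
  }
  list(manifest = manifest, make_cell = make_cell)
}

#' Write a repair time-course manifest as TSV
#'
#' @param manifest the manifest data.frame from
#'   [simulate_repair_timecourse()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read an image stack as per-channel multi-page TIFF
#'
#' Each channel goes to `<dir>/<name>.tif` as 16-bit pages (one per
#' z-plane); intensities are stored as counts scaled by 1/65535, so integer
#' counts below 65536 round-trip exactly. Voxel size is written alongside as
#' `voxel_size.txt`.
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_tiff <- function(stack, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    if (max(ch) > 65535) stop("channel '", nm, "' exceeds 16-bit range")
    pages <- lapply(seq_len(dim(ch)[3]),
                    function(z) t(ch[, , z]) / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L)
  }
  writeLines(paste(stack$voxel_size, collapse = "\t"),
             file.path(dir, "voxel_size.txt"))
  invisible(dir)
}

#' @rdname write_stack_tiff
#' @param channels channel names to read (defaults to all `.tif` files in
#'   `dir`).
#' @export
read_stack_tiff <- function(dir, channels = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  vs <- as.numeric(strsplit(readLines(file.path(dir, "voxel_size.txt")),
                            "\t")[[1]])
  if (is.null(channels))
    channels <- sub("\\.tif$", "", list.files(dir, pattern = "\\.tif$"))
  chs <- lapply(channels, function(nm) {
    pages <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")), all = TRUE)
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
    round(arr * 65535)
  })
  names(chs) <- channels
  image_stack(chs, voxel_size = vs)
}
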