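#' Configuration for S-phase substage classification
#'
#' Tunable thresholds for the rule-based classifier in [classify_sphase()].
#'
#' @param edu_min_mean minimum background-subtracted in-nucleus mean EdU
#'   intensity for a cell to count as EdU-positive (S phase); below it the
#'   call is non-S. Units: intensity counts.
#' @param late_max_foci maximum focus count compatible with the late-S
#'   pattern of few distinct spots.
#' @param late_min_volume minimum mean focus volume (um^3) for the late-S
#'   call.
#' @param mid_min_peripheral minimum fraction of EdU intensity inside the
#'   peripheral shell for the mid-S (peri-nuclear) call.
#' @param shell_um thickness of the peripheral shell (um; the 1-um erosion
#'   shell).
#' @param foci_k_sd,focus_min_volume,size_guide focus-detection settings
#'   passed to [segment_foci()] for EdU foci (replication foci are smaller
#'   than repair foci, hence the lower minimum volume).
#' @return list of settings.
#' @export
sphase_config <- function(edu_min_mean = 5, late_max_foci = 25,
                          late_min_volume = 0.8, mid_min_peripheral = 0.5,
                          shell_um = 1, foci_k_sd = 3,
                          focus_min_volume = 0.02, size_guide = 1) {
  list(edu_min_mean = edu_min_mean, late_max_foci = late_max_foci,
       late_min_volume = late_min_volume,
       mid_min_peripheral = mid_min_peripheral, shell_um = shell_um,
       foci_k_sd = foci_k_sd, focus_min_volume = focus_min_volume,
       size_guide = size_guide)
}

#' Classify the S-phase substage from the EdU pattern
#'
#' Rule-based call reproducing the visual criteria for replication-focus
#' patterns: early S shows many small EdU foci throughout the nuclear
#' interior; mid S concentrates foci at the nuclear periphery; late S shows
#' few distinct large spots; EdU-negative nuclei are non-S. The decision
#' rule, applied to the background-subtracted EdU channel, is:
#' EdU-negative (mean below `edu_min_mean`) -> non-S; else late if
#' `n_foci <= late_max_foci` and the mean focus volume is at least
#' `late_min_volume`; else mid if the peripheral intensity fraction (EdU in
#' a `shell_um` erosion shell over total) is at least `mid_min_peripheral`;
#' else early.
#'
#' @param edu 3D EdU-channel array (raw; background subtraction is applied
#'   internally).
#' @param nucleus `nucleus_mask` or logical array for one nucleus.
#' @param voxel_size `c(dx, dy, dz)` um (from `nucleus` if a
#'   `nucleus_mask`).
#' @param config see [sphase_config()].
#' @param radius_px background-subtraction radius ([local_mean_subtract()]).
#' @return an `sphase_call`: list with `label` in
#'   `c("early", "mid", "late", "non-S")` and `features`
#'   (mean_edu, peripheral_fraction, n_foci, mean_focus_volume,
#'   interior_dispersion). Always returns a call.
#' @export
classify_sphase <- function(edu, nucleus, voxel_size = NULL,
                            config = sphase_config(), radius_px = 10L) {
  if (inherits(nucleus, "nucleus_mask")) {
    if (is.null(voxel_size)) voxel_size <- nucleus$voxel_size
  }
  if (is.null(voxel_size)) stop("voxel_size required")
  nuc <- .as_mask(nucleus)
  if (!any(nuc)) stop("empty nucleus mask")

  sub <- local_mean_subtract(edu, radius_px)
  mean_edu <- mean(sub[nuc])

  depth <- depth_map_um(nuc, voxel_size)
  shell <- nuc & depth <= config$shell_um
  tot <- sum(sub[nuc])
  peripheral_fraction <- if (tot > 0) sum(sub[shell]) / tot else NA_real_

  foci <- segment_foci(sub, nucleus, voxel_size,
                       k_sd = config$foci_k_sd,
                       min_volume = config$focus_min_volume,
                       size_guide = config$size_guide)
  n_foci <- nrow(foci$table)
  mean_focus_volume <- if (n_foci > 0) mean(foci$table$volume_um3) else 0

  # intensity-weighted spread of normalised depth: high for interior-filling
  # patterns, low for rim- or spot-concentrated ones (reported, not used in
  # the decision rule)
  interior_dispersion <- if (tot > 0 && max(depth) > 0) {
    nd <- depth[nuc] / max(depth)
    w <- sub[nuc] / tot
    mu <- sum(w * nd)
    sqrt(sum(w * (nd - mu)^2))
  } else NA_real_

  label <- if (mean_edu < config$edu_min_mean) {
    "non-S"
  } else if (n_foci > 0 && n_foci <= config$late_max_foci &&
             mean_focus_volume >= config$late_min_volume) {
    "late"
  } else if (!is.na(peripheral_fraction) &&
             peripheral_fraction >= config$mid_min_peripheral) {
    "mid"
  } else {
    "early"
  }
  structure(list(label = label,
                 features = c(mean_edu = mean_edu,
                              peripheral_fraction = peripheral_fraction,
                              n_foci = n_foci,
                              mean_focus_volume = mean_focus_volume,
                              interior_dispersion = interior_dispersion)),
            class = "sphase_call")
}

#' @export
print.sphase_call <- function(x, ...) {
  cat(sprintf("sphase_call: %s (EdU mean %.1f, peripheral %.2f, %d foci)\n",
              x$label, x$features[["mean_edu"]],
              x$features[["peripheral_fraction"]],
              as.integer(x$features[["n_foci"]])))
  invisible(x)
}

#' Stage cells by DNA content (G1 / S / G2)
#'
#' EdU-positive cells are in S phase. EdU-negative cells are split into G1
#' and G2 by 2-class clustering (k-means, deterministically initialised at
#' the extreme cells) on standardised nuclear volume and integrated DNA
#' (DAPI) intensity; the cluster with the lower mean DNA content is G1.
#'
#' @param dapi_total integrated DAPI intensity per cell.
#' @param volume nuclear volume per cell (um^3).
#' @param edu_positive logical per cell.
#' @return character vector of stages, one per cell. A single EdU-negative
#'   cell cannot be clustered and is assigned G1 with a warning.
#' @export
dna_content_stage <- function(dapi_total, volume, edu_positive) {
  n <- length(dapi_total)
  stopifnot(length(volume) == n, length(edu_positive) == n)
  stage <- rep(NA_character_, n)
  stage[edu_positive] <- "S"
  neg <- which(!edu_positive)
  if (length(neg) == 0L) return(stage)
  if (length(neg) == 1L) {
    warning("single EdU-negative cell; assigned to G1")
    stage[neg] <- "G1"
    return(stage)
  }
  m <- scale(cbind(volume[neg], dapi_total[neg]))
  m[is.nan(m)] <- 0  # constant column: no information, drop its spread
  centers <- m[c(which.min(m[, 2]), which.max(m[, 2])), , drop = FALSE]
  if (all(centers[1, ] == centers[2, ])) {  # all cells identical
    stage[neg] <- "G1"
    return(stage)
  }
  km <- stats::kmeans(m, centers = centers)
  mean_dapi <- tapply(dapi_total[neg], km$cluster, mean)
  g1_cluster <- as.integer(names(which.min(mean_dapi)))
  stage[neg] <- ifelse(km$cluster == g1_cluster, "G1", "G2")
  stage
}
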