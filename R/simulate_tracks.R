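# deterministic sub-seed derivation so that every cell / draw has its own
# reproducible stream while the user supplies one global seed
.subseed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                index * 1299721) %% 2147483647)
}

#' Simulate feature tracks with a planted Spearman correlation structure
#'
#' Gaussian copula: a latent multivariate normal is drawn with Pearson
#' correlation `rho_latent = 2 * sin(pi * rho_S / 6)` — the inverse of the
#' Gaussian-copula Spearman map, so continuous margins realise the target
#' Spearman matrix exactly in expectation — and pushed through the requested
#' marginal distributions. Count margins (Poisson) introduce ties and a
#' slight attenuation of the realised Spearman correlation.
#'
#' @param n_intervals number of grid intervals to simulate.
#' @param target_spearman symmetric target Spearman matrix (unit diagonal,
#'   entries in `[-1, 1]`); must be positive semi-definite on the latent
#'   scale.
#' @param marginals list of per-track marginal specs, each a list with
#'   `type` in `c("normal", "lognormal", "uniform", "poisson")` and its
#'   parameters (`mean`, `sd` / `meanlog`, `sdlog` / `lambda`). Defaults to
#'   standard normal margins for every track.
#' @param labels track labels (default track1, track2, ...).
#' @param seed integer seed.
#' @param width interval width of the synthetic grid (bp).
#' @return list with `tracks` (named list of `feature_track` on a synthetic
#'   single-chromosome grid), `grid`, and `truth` (the target matrix).
#' @export
simulate_tracks <- function(n_intervals, target_spearman,
                            marginals = NULL, labels = NULL, seed = 1L,
                            width = 10000L) {
  k <- nrow(target_spearman)
  stopifnot(ncol(target_spearman) == k,
            isTRUE(all.equal(target_spearman, t(target_spearman))),
            all(abs(target_spearman) <= 1),
            all(diag(target_spearman) == 1))
  if (is.null(marginals))
    marginals <- replicate(k, list(type = "normal"), simplify = FALSE)
  stopifnot(length(marginals) == k)
  if (is.null(labels)) labels <- paste0("track", seq_len(k))

  rho_lat <- 2 * sin(pi * target_spearman / 6)
  diag(rho_lat) <- 1
  ev <- eigen(rho_lat, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("target Spearman matrix is not attainable (latent matrix not PSD)")
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), k) %*% t(ev$vectors)

  set.seed(seed)
  z <- matrix(stats::rnorm(n_intervals * k), n_intervals, k) %*% A
  u <- stats::pnorm(z)

  grid <- bin_genome(c(sim = n_intervals * width), width = width)
  tracks <- vector("list", k)
  for (j in seq_len(k)) {
    mg <- marginals[[j]]
    vals <- switch(mg$type,
      normal = stats::qnorm(u[, j], mean = mg$mean %||% 0, sd = mg$sd %||% 1),
      lognormal = stats::qlnorm(u[, j], meanlog = mg$meanlog %||% 0,
                                sdlog = mg$sdlog %||% 1),
      uniform = u[, j],
      poisson = stats::qpois(u[, j], lambda = mg$lambda %||% 3),
      stop("unknown marginal type: ", mg$type))
    tracks[[j]] <- feature_track(vals, grid, labels[j])
  }
  names(tracks) <- labels
  list(tracks = tracks, grid = grid, truth = target_spearman)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a count track plus a track pair whose correlation differs
#' between repeat-rich and repeat-poor intervals
#'
#' Emulates the stratified-correlation design: interval element counts come
#' from a zero-inflated Poisson (a `p_zero` point mass at zero — repeat-poor
#' deserts — otherwise Poisson(`lambda`)), and two continuous tracks are
#' drawn with latent correlation `rho_rich` on rich intervals
#' (count > `threshold_rich`), `rho_poor` on poor intervals (count == 0) and
#' their mean elsewhere.
#'
#' @param n_intervals intervals to simulate.
#' @param lambda Poisson mean of the non-zero count component (default 15,
#'   giving a large > 10 stratum).
#' @param p_zero zero-inflation probability (default 0.3).
#' @param rho_rich,rho_poor target Spearman correlation of the pair within
#'   each stratum.
#' @param threshold_rich rich cutoff (count strictly greater; default 10).
#' @param seed integer seed.
#' @return list with `tracks` (counts, x, y), `grid`, and `truth`
#'   (rho_rich, rho_poor, rich/poor index sets).
#' @export
simulate_stratified_tracks <- function(n_intervals, lambda = 15,
                                       p_zero = 0.3, rho_rich = 0.2,
                                       rho_poor = 0.7, threshold_rich = 10,
                                       seed = 1L) {
  set.seed(seed)
  zero <- stats::runif(n_intervals) < p_zero
  counts <- ifelse(zero, 0L, stats::rpois(n_intervals, lambda))
  rich <- which(counts > threshold_rich)
  poor <- which(counts == 0L)

  rho_s <- rep((rho_rich + rho_poor) / 2, n_intervals)
  rho_s[rich] <- rho_rich
  rho_s[poor] <- rho_poor
  rho_l <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(n_intervals)
  z2 <- rho_l * z1 + sqrt(1 - rho_l^2) * stats::rnorm(n_intervals)

  grid <- bin_genome(c(sim = n_intervals * 10000), width = 10000L)
  list(tracks = list(counts = feature_track(counts, grid, "counts"),
                     x = feature_track(z1, grid, "x"),
                     y = feature_track(z2, grid, "y")),
       grid = grid,
       truth = list(rho_rich = rho_rich, rho_poor = rho_poor,
                    rich_indices = rich, poor_indices = poor))
}

#' Simulate reads over an annotated toy genome with known class truth
#'
#' Builds a single-chromosome toy genome of interleaved repeat blocks
#' (default classes Alu, LINE, SAT, LTR with copy lengths 300, 1000, 800 and
#' 500 bp, separated by 400-bp non-repeat gaps) and draws reads with known
#' ground truth: each read is non-repeat with probability `nonrepeat_rate`
#' (one placement inside a gap, truth NONREPEAT); otherwise its true class
#' follows `proportions` and it is placed fully inside a random copy of that
#' class. With probability `multimap_rate` a classed read is multi-mapped:
#' a cross-class multi-mapper (probability `cross_class_frac` among
#' multi-mappers) gains a placement inside a different class, making its
#' truth DISCARD; a within-class multi-mapper gains 1-3 extra placements in
#' other copies of its own class and keeps its class truth. Block gaps
#' exceed the read length, so every placement overlaps exactly the intended
#' annotation and the truth label is the provably unique correct assignment.
#'
#' @param n_reads number of reads.
#' @param proportions named class proportions (must sum to 1).
#' @param multimap_rate fraction of classed reads that are multi-mapped.
#' @param cross_class_frac fraction of multi-mappers that are cross-class.
#' @param nonrepeat_rate fraction of reads placed outside any repeat.
#' @param genome_length toy genome length (bp).
#' @param read_length read length (bp; default 36).
#' @param seed integer seed.
#' @return list with `placements` (read_id, chrom, start, end),
#'   `annotations` (BED-style data.frame with repeat_class/repeat_name),
#'   `truth` (read_id, truth label), and `chrom_sizes`.
#' @export
simulate_reads <- function(n_reads = 20000L,
                           proportions = c(Alu = 0.4, LINE = 0.3,
                                           SAT = 0.2, LTR = 0.1),
                           multimap_rate = 0.2, cross_class_frac = 0.2,
                           nonrepeat_rate = 0.05, genome_length = 1e6,
                           read_length = 36L, seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9,
            multimap_rate >= 0, multimap_rate <= 1,
            cross_class_frac >= 0, cross_class_frac <= 1)
  classes <- names(proportions)
  copy_len <- stats::setNames(
    rep_len(c(300L, 1000L, 800L, 500L), length(classes)), classes)
  gap <- 400L
  stopifnot(read_length < gap, read_length < min(copy_len))

  # lay out interleaved blocks: class1 gap class2 gap ... up to genome_length
  ann <- list(); pos <- gap
  repeat {
    done <- FALSE
    for (cl in classes) {
      if (pos + copy_len[[cl]] + gap > genome_length) { done <- TRUE; break }
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = "toy1", start = pos, end = pos + copy_len[[cl]],
        repeat_class = cl, stringsAsFactors = FALSE)
      pos <- pos + copy_len[[cl]] + gap
    }
    if (done) break
  }
  annotations <- do.call(rbind, ann)
  annotations$repeat_name <- paste0(annotations$repeat_class, "_",
                                    stats::ave(seq_len(nrow(annotations)),
                                               annotations$repeat_class,
                                               FUN = seq_along))
  copies <- split(seq_len(nrow(annotations)), annotations$repeat_class)
  # gap midpoints available for non-repeat placements
  gap_starts <- c(0L, annotations$end)
  gap_ends <- c(annotations$start, as.integer(genome_length))
  gaps <- cbind(gap_starts, gap_ends)[gap_ends - gap_starts >= gap, , drop = FALSE]

  set.seed(seed)
  place_in <- function(row_idx) {
    a <- annotations[row_idx, ]
    s <- a$start + sample.int(a$end - a$start - read_length + 1L, 1L) - 1L
    c(s, s + read_length)
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  u <- stats::runif(n_reads)
  truth <- character(n_reads)
  pl <- vector("list", n_reads)
  cum <- cumsum(proportions)
  for (i in seq_len(n_reads)) {
    if (u[i] < nonrepeat_rate) {
      g <- gaps[sample.int(nrow(gaps), 1L), ]
      s <- g[1] + sample.int(g[2] - g[1] - read_length + 1L, 1L) - 1L
      pl[[i]] <- cbind(s, s + read_length)
      truth[i] <- "NONREPEAT"
      next
    }
    cl <- classes[findInterval((u[i] - nonrepeat_rate) / (1 - nonrepeat_rate),
                               cum, left.open = TRUE) + 1L]
    first <- place_in(sample(copies[[cl]], 1L))
    if (stats::runif(1) < multimap_rate) {
      if (stats::runif(1) < cross_class_frac) {
        other <- sample(setdiff(classes, cl), 1L)
        second <- place_in(sample(copies[[other]], 1L))
        pl[[i]] <- rbind(first, second)
        truth[i] <- "DISCARD"
      } else {
        k <- sample(1:3, 1L)
        extra <- t(vapply(sample(copies[[cl]], k), place_in, c(0, 0)))
        pl[[i]] <- rbind(first, extra)
        truth[i] <- cl
      }
    } else {
      pl[[i]] <- cbind(first[1], first[2])
      truth[i] <- cl
    }
  }
  n_per <- vapply(pl, nrow, 0L)
  placements <- data.frame(
    read_id = rep(ids, n_per),
    chrom = "toy1",
    start = as.integer(unlist(lapply(pl, function(m) m[, 1]))),
    end = as.integer(unlist(lapply(pl, function(m) m[, 2]))),
    stringsAsFactors = FALSE)
  list(placements = placements, annotations = annotations,
       truth = data.frame(read_id = ids, truth = truth,
                          stringsAsFactors = FALSE),
       chrom_sizes = c(toy1 = as.integer(genome_length)))
}
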