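#' Spearman rank correlation with pairwise missing-removal
#'
#' Spearman's rho: the Pearson correlation of average fractional ranks (ties
#' share their mean rank). Pairs with a missing value in either vector are
#' dropped first and the number retained reported as `n_used`. The p-value
#' uses the asymptotic t approximation (no exact permutation p under ties).
#' Degenerate inputs (fewer than 3 complete pairs, or a constant vector) give
#' a missing rho with a reason code rather than an error, so matrix cells can
#' record why they are empty.
#'
#' @param x,y numeric vectors of equal length (or `feature_track`s on a
#'   shared grid).
#' @return list with `rho`, `pvalue`, `n_used`, and `reason` (`NA` unless rho
#'   is missing; one of "too_few_pairs", "constant_input").
#' @examples
#' spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4))$rho  # 0.9487
#' @export
spearman_rho <- function(x, y) {
  if (inherits(x, "feature_track")) x <- x$values
  if (inherits(y, "feature_track")) y <- y$values
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(rho = NA_real_, pvalue = NA_real_, n_used = n,
                reason = "too_few_pairs"))
  xs <- x[ok]; ys <- y[ok]
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L)
    return(list(rho = NA_real_, pvalue = NA_real_, n_used = n,
                reason = "constant_input"))
  rho <- stats::cor(xs, ys, method = "spearman")
  pv <- suppressWarnings(
    stats::cor.test(xs, ys, method = "spearman", exact = FALSE)$p.value)
  list(rho = rho, pvalue = pv, n_used = n, reason = NA_character_)
}

#' Spearman correlation matrix between two track sets
#'
#' Cell-wise [spearman_rho()] between every row track and every column track,
#' with pairwise missing-removal per cell; label order is as given.
#'
#' @param tracks_rows,tracks_cols lists of `feature_track`s sharing one grid
#'   (a single track may be passed bare).
#' @return a `correlation_matrix`: list of matrices `rho`, `pvalue`, `n_used`
#'   and a character matrix `reason`, with track labels as dimnames.
#' @export
correlation_matrix <- function(tracks_rows, tracks_cols = tracks_rows) {
  as_list <- function(x) if (inherits(x, "feature_track")) list(x) else x
  tracks_rows <- as_list(tracks_rows); tracks_cols <- as_list(tracks_cols)
  all_tr <- c(tracks_rows, tracks_cols)
  g <- all_tr[[1]]$grid
  for (tr in all_tr)
    if (!.same_grid(tr$grid, g)) stop("tracks on mismatched grids")

  rlab <- vapply(tracks_rows, `[[`, "", "label")
  clab <- vapply(tracks_cols, `[[`, "", "label")
  dims <- list(rlab, clab)
  rho <- matrix(NA_real_, length(rlab), length(clab), dimnames = dims)
  pv <- rho; n_used <- rho
  reason <- matrix(NA_character_, length(rlab), length(clab), dimnames = dims)
  for (i in seq_along(tracks_rows)) {
    for (j in seq_along(tracks_cols)) {
      res <- spearman_rho(tracks_rows[[i]]$values, tracks_cols[[j]]$values)
      rho[i, j] <- res$rho; pv[i, j] <- res$pvalue
      n_used[i, j] <- res$n_used; reason[i, j] <- res$reason
    }
  }
  structure(list(rho = rho, pvalue = pv, n_used = n_used, reason = reason),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (rho):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Write a correlation matrix as TSV files
#'
#' Writes `<prefix>.rho.tsv`, `<prefix>.pvalue.tsv` and `<prefix>.n.tsv`.
#'
#' @param cm a `correlation_matrix`.
#' @param prefix output path prefix.
#' @export
write_correlation_tsv <- function(cm, prefix) {
  for (part in c("rho", "pvalue", "n_used")) {
    utils::write.table(cm[[part]], paste0(prefix, ".", sub("_used", "", part), ".tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(prefix)
}

#' Stratify grid intervals into repeat-rich and repeat-poor sets
#'
#' Mirrors the L1-rich / L1-poor contrast: "rich" intervals carry strictly
#' more than `threshold_rich` elements (default > 10 per 10 kb interval),
#' "poor" intervals carry exactly `threshold_poor` (default 0, i.e. none).
#'
#' @param count_track integer-valued `feature_track` of element counts.
#' @param threshold_rich rich cutoff (value strictly greater).
#' @param threshold_poor poor value (exact equality).
#' @return a `stratified_selection`: list with `rich_indices`, `poor_indices`
#'   and the thresholds. Empty strata warn.
#' @export
stratify_intervals <- function(count_track, threshold_rich = 10,
                               threshold_poor = 0) {
  v <- if (inherits(count_track, "feature_track")) count_track$values else count_track
  if (any(v[!is.na(v)] != round(v[!is.na(v)])))
    stop("count track must be integer-valued")
  rich <- which(!is.na(v) & v > threshold_rich)
  poor <- which(!is.na(v) & v == threshold_poor)
  if (length(rich) == 0L) warning("rich stratum is empty")
  if (length(poor) == 0L) warning("poor stratum is empty")
  structure(list(rich_indices = rich, poor_indices = poor,
                 threshold_rich = threshold_rich,
                 threshold_poor = threshold_poor),
            class = "stratified_selection")
}

.subset_track <- function(tr, idx) {
  v <- rep(NA_real_, length(tr$values))
  v[idx] <- tr$values[idx]
  feature_track(v, tr$grid, tr$label)
}

#' Correlation matrices restricted to rich and poor strata
#'
#' Runs [correlation_matrix()] twice, once per stratum, by masking intervals
#' outside each index set (so `n_used` reflects the stratum size after
#' missing-removal). Cells with fewer than 3 usable pairs are missing with a
#' reason, not an error.
#'
#' @param tracks_rows,tracks_cols lists of `feature_track`s.
#' @param selection a `stratified_selection` from [stratify_intervals()].
#' @return list with elements `rich` and `poor`, each a
#'   `correlation_matrix`.
#' @export
stratified_matrix <- function(tracks_rows, tracks_cols, selection) {
  stopifnot(inherits(selection, "stratified_selection"))
  as_list <- function(x) if (inherits(x, "feature_track")) list(x) else x
  tracks_rows <- as_list(tracks_rows); tracks_cols <- as_list(tracks_cols)
  sub_all <- function(trs, idx) lapply(trs, .subset_track, idx = idx)
  list(
    rich = correlation_matrix(sub_all(tracks_rows, selection$rich_indices),
                              sub_all(tracks_cols, selection$rich_indices)),
    poor = correlation_matrix(sub_all(tracks_rows, selection$poor_indices),
                              sub_all(tracks_cols, selection$poor_indices))
  )
}
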