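# Independent oracles and small image builders used across tests.
# These deliberately avoid the package's own code paths (and rank()/cor()
# conveniences where they are the thing under test).

# average fractional ranks by explicit sort + tie-group averaging
oracle_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Pearson correlation from explicit sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  num <- sum(a * b) - sa * sb / n
  den <- sqrt((sum(a^2) - sa^2 / n) * (sum(b^2) - sb^2 / n))
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_ranks(x), oracle_ranks(y))

# brute-force read classification: set of repeat classes overlapped by each
# placement (data.frame scan, no interval index), then the counting rule
oracle_classify_one <- function(pl, ann) {
  classes <- character(0)
  any_nonrep <- FALSE
  for (i in seq_len(nrow(pl))) {
    hit <- ann$repeat_class[ann$chrom == pl$chrom[i] &
                              ann$start < pl$end[i] & ann$end > pl$start[i]]
    if (length(hit) == 0L) any_nonrep <- TRUE else classes <- c(classes, hit)
  }
  classes <- unique(classes)
  if (length(classes) == 0L) return("NONREPEAT")
  if (length(classes) >= 2L) return("DISCARD")
  if (any_nonrep) return("DISCARD")
  classes
}

oracle_classify <- function(placements, ann) {
  ids <- unique(placements$read_id)
  vapply(ids, function(id)
    oracle_classify_one(placements[placements$read_id == id, , drop = FALSE],
                        ann), "", USE.NAMES = TRUE)
}

# anisotropic Gaussian blob on a voxel grid (physical-um center and sigma)
blob3 <- function(d, vs, ctr, sigma, peak) {
  x <- (seq_len(d[1]) - 0.5) * vs[1]
  y <- (seq_len(d[2]) - 0.5) * vs[2]
  z <- (seq_len(d[3]) - 0.5) * vs[3]
  peak * outer(outer(exp(-(x - ctr[1])^2 / (2 * sigma[1]^2)),
                     exp(-(y - ctr[2])^2 / (2 * sigma[2]^2))),
               exp(-(z - ctr[3])^2 / (2 * sigma[3]^2)))
}

# binary ellipsoid nucleus (physical um center/semi-axes)
ellipsoid3 <- function(d, vs, ctr, semi) {
  x <- ((seq_len(d[1]) - 0.5) * vs[1] - ctr[1]) / semi[1]
  y <- ((seq_len(d[2]) - 0.5) * vs[2] - ctr[2]) / semi[2]
  z <- ((seq_len(d[3]) - 0.5) * vs[3] - ctr[3]) / semi[3]
  array(outer(outer(x^2, y^2, "+"), z^2, "+") <= 1, d)
}

# linear-interpolation quantile computed from the definition
oracle_quantile7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
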