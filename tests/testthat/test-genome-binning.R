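test_that("bin_genome tiles chromosomes into half-open fixed-width intervals", {
  g <- bin_genome(c(chrA = 25000), width = 10000)
  expect_equal(grid_intervals(g),
               data.frame(chrom = "chrA",
                          start = c(0L, 10000L, 20000L),
                          end = c(10000L, 20000L, 25000L)))
  expect_length(bin_genome(c(chrA = 10000), 10000), 1L)

  # tiling completeness across several chromosomes and widths
  sizes <- c(c1 = 123456, c2 = 99999, c3 = 5000)
  for (w in c(1000, 10000, 7777)) {
    iv <- grid_intervals(bin_genome(sizes, w))
    lens <- tapply(iv$end - iv$start, iv$chrom, sum)
    expect_equal(as.numeric(lens[names(sizes)]), as.numeric(sizes))
    expect_true(all(iv$end - iv$start <= w))
  }
  expect_error(bin_genome(stats::setNames(numeric(0), character(0))),
               "no chromosomes")
  expect_error(bin_genome(c(chrA = 0), 100))
})

test_that("the hg19 chromosome lengths tile into more than 290,000 10-kb intervals", {
  # GRCh37/hg19 primary assembly chromosome lengths (bp)
  hg19 <- c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430,
            chr4 = 191154276, chr5 = 180915260, chr6 = 171115067,
            chr7 = 159138663, chr8 = 146364022, chr9 = 141213431,
            chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
            chr13 = 115169878, chr14 = 107349540, chr15 = 102531392,
            chr16 = 90354753, chr17 = 81195210, chr18 = 78077248,
            chr19 = 59128983, chr20 = 63025520, chr21 = 48129895,
            chr22 = 51304566, chrX = 155270560, chrY = 59373566)
  n <- sum(ceiling(hg19 / 10000))
  expect_gt(n, 290000)
  # same arithmetic as bin_genome without materialising 300k ranges
  g <- bin_genome(hg19[c("chr21", "chr22")], 10000)
  expect_length(g, sum(ceiling(hg19[c("chr21", "chr22")] / 10000)))
})

test_that("count_elements uses the midpoint rule and conserves counts", {
  g <- bin_genome(c(chrA = 25000), 10000)
  expect_equal(count_elements(g, data.frame(chrom = "chrA", start = 9500,
                                            end = 9800))$values,
               c(1, 0, 0))
  # boundary-spanning element: midpoint 10000 falls in interval 2 (half-open)
  expect_equal(count_elements(g, data.frame(chrom = "chrA", start = 9900,
                                            end = 10100))$values,
               c(0, 1, 0))

  set.seed(42)
  n <- 1000
  s <- sample.int(24900, n)
  tr <- count_elements(g, data.frame(chrom = "chrA", start = s, end = s + 50))
  expect_equal(sum(tr$values), n)

  # off-grid chromosome: warn, skip, report
  expect_warning(
    tr2 <- count_elements(g, data.frame(chrom = c("chrA", "chrZ"),
                                        start = c(0, 0), end = c(10, 10))),
    "skipped")
  expect_equal(sum(tr2$values), 1)
  expect_equal(attr(tr2, "n_skipped"), 1L)
})

test_that("count_elements filters by repeat class", {
  g <- bin_genome(c(chrA = 30000), 10000)
  ann <- data.frame(chrom = "chrA", start = c(100, 10100, 20100, 150),
                    end = c(400, 10400, 20400, 450),
                    repeat_class = c("Alu", "L1", "Alu", "Alu"))
  expect_equal(count_elements(g, ann, class_filter = "Alu")$values, c(2, 0, 1))
  expect_equal(count_elements(g, ann, class_filter = "L1")$values, c(0, 1, 0))
  expect_equal(count_elements(g, ann, class_filter = "L1")$label, "L1")
})

test_that("gc_track computes per-interval GC and flags all-N intervals", {
  g <- bin_genome(c(chrA = 24), 8)
  fa <- Biostrings::DNAStringSet(c(chrA = paste0("GGCCAATT", "GCGC", "NNNN",
                                                 "NNNNNNNN")))
  tr <- gc_track(g, fa)
  expect_equal(tr$values, c(0.5, 1.0, NA))

  # reverse complement leaves GC identical
  seq <- paste(sample(c("A", "C", "G", "T"), 64, replace = TRUE), collapse = "")
  g2 <- bin_genome(c(s = 64), 16)
  fwd <- gc_track(g2, Biostrings::DNAStringSet(c(s = seq)))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- gc_track(g2, Biostrings::DNAStringSet(c(s = rc)))
  expect_equal(sort(fwd$values), sort(rev$values))
  expect_equal(mean(fwd$values), mean(rev$values))

  expect_error(gc_track(bin_genome(c(chrB = 10), 10), fa), "chrB")
})

test_that("rpkm_track normalises by true interval length and library size", {
  g <- bin_genome(c(chrA = 25000), 10000)
  reads <- data.frame(chrom = "chrA", pos = rep(5000L, 200))
  expect_equal(rpkm_track(g, reads, 20e6)$values, c(1, 0, 0))
  expect_equal(rpkm_track(g, reads[0, ], 20e6)$values, c(0, 0, 0))
  # 5-kb terminal interval, 50 reads, 1e6 library
  reads2 <- data.frame(chrom = "chrA", pos = rep(21000L, 50))
  expect_equal(rpkm_track(g, reads2, 1e6)$values, c(0, 0, 10))

  # linearity: doubling counts and library size leaves RPKM unchanged
  set.seed(7)
  rr <- data.frame(chrom = "chrA", pos = sample.int(25000, 500) - 1L)
  t1 <- rpkm_track(g, rr, 2e6)
  t2 <- rpkm_track(g, rbind(rr, rr), 4e6)
  expect_equal(t1$values, t2$values)

  expect_error(rpkm_track(g, rr, 0), "total_mapped_reads")
})

test_that("feature tracks validate length and flag missing explicitly", {
  g <- bin_genome(c(chrA = 30000), 10000)
  expect_error(feature_track(1:2, g), "intervals")
  tr <- feature_track(c(1, NA, 3), g, "t")
  expect_equal(sum(is.na(tr$values)), 1L)
  expect_error(feature_track(c(1, Inf, 3), g), "finite")
})
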