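ann4 <- data.frame(
  chrom = "c",
  start = c(100L, 1000L, 2000L, 3000L, 4000L),
  end = c(400L, 1400L, 2300L, 3400L, 4500L),
  repeat_class = c("Alu", "Alu", "L1", "Alu", "L1"),
  stringsAsFactors = FALSE)

test_that("classify_read follows the single-class signature rule", {
  one <- function(starts, ends) {
    data.frame(read_id = "r", chrom = "c", start = starts, end = ends)
  }
  # unique placement inside an Alu copy
  expect_equal(classify_read(one(150, 186), ann4), "Alu")
  # three placements in three different Alu copies: still Alu
  expect_equal(classify_read(one(c(150, 1050, 3050), c(186, 1086, 3086)),
                             ann4), "Alu")
  # placements in one Alu and one L1: discarded
  expect_equal(classify_read(one(c(150, 2050), c(186, 2086)), ann4),
               "DISCARD")
  # no placement in any repeat
  expect_equal(classify_read(one(500, 536), ann4), "NONREPEAT")
  # mixed repeat / non-repeat multi-mapping: discarded by default ...
  expect_equal(classify_read(one(c(150, 500), c(186, 536)), ann4), "DISCARD")
  # ... but counted by class under the alternative policy
  expect_equal(classify_read(one(c(150, 500), c(186, 536)), ann4,
                             mixed_policy = "class"), "Alu")
  # single placement straddling two classes counts both and discards
  ann_ov <- rbind(ann4, data.frame(chrom = "c", start = 380L, end = 600L,
                                   repeat_class = "L1"))
  expect_equal(classify_read(one(390, 426), ann_ov), "DISCARD")
  # 1-bp overlap suffices
  expect_equal(classify_read(one(399, 435), ann4), "Alu")
  expect_equal(classify_read(one(400, 436), ann4), "NONREPEAT")
})

test_that("classify_reads applies the grouping map before the rule", {
  ann <- data.frame(chrom = "c", start = c(0L, 100L), end = c(50L, 150L),
                    repeat_class = c("AluYa5", "AluSx"))
  pl <- data.frame(read_id = "r", chrom = "c", start = c(10L, 110L),
                   end = c(40L, 140L))
  # without grouping the two family names look like different classes
  expect_equal(unname(classify_reads(pl, ann)), "DISCARD")
  expect_equal(unname(classify_reads(pl, ann,
                                     grouping = c(AluYa5 = "Alu",
                                                  AluSx = "Alu"))), "Alu")
})

test_that("classification conserves reads and is invariant to duplication", {
  sim <- simulate_reads(n_reads = 2000, seed = 21)
  asn <- classify_reads(sim$placements, sim$annotations)
  cc <- count_repeat_classes(asn, timepoint = "0h")
  expect_equal(sum(cc$counts) + cc$n_nonrepeat + cc$n_discarded, cc$n_total)
  expect_equal(cc$n_total, 2000L)

  fr <- metarepeat_fractions(cc)
  expect_equal(sum(fr), 1, tolerance = 1e-12)

  # duplicating every read leaves fractions unchanged
  dup <- sim$placements
  dup$read_id <- paste0(dup$read_id, "_dup")
  asn2 <- classify_reads(rbind(sim$placements, dup), sim$annotations)
  fr2 <- metarepeat_fractions(count_repeat_classes(asn2))
  expect_equal(fr2[names(fr)], fr, tolerance = 1e-12)
})

test_that("classify_reads equals the brute-force oracle on random reads", {
  sim <- simulate_reads(n_reads = 1000, seed = 22)
  asn <- classify_reads(sim$placements, sim$annotations)
  orc <- oracle_classify(sim$placements, sim$annotations)
  expect_equal(asn[names(orc)], orc)
})

test_that("metarepeat_fractions normalises over single-class reads only", {
  cc <- structure(list(timepoint = "0.5h",
                       counts = c(Alu = 470L, LINE = 240L, SAT = 150L,
                                  LTR = 140L),
                       n_nonrepeat = 100L, n_discarded = 50L,
                       n_total = 1150L),
                  class = "repeat_class_counts")
  expect_equal(metarepeat_fractions(cc),
               c(Alu = 0.47, LINE = 0.24, SAT = 0.15, LTR = 0.14))
  # restricting the denominator re-normalises
  expect_equal(sum(metarepeat_fractions(cc, classes = c("Alu", "LINE"))), 1)

  single <- structure(list(timepoint = NA, counts = c(Alu = 10L),
                           n_nonrepeat = 0L, n_discarded = 0L, n_total = 10L),
                      class = "repeat_class_counts")
  expect_equal(metarepeat_fractions(single), c(Alu = 1.0))
  none <- structure(list(timepoint = NA, counts = integer(0),
                         n_nonrepeat = 5L, n_discarded = 5L, n_total = 10L),
                    class = "repeat_class_counts")
  expect_error(metarepeat_fractions(none), "no classifiable reads")
})

test_that("relative_enrichment is a ratio of fractions with identity at baseline", {
  mk <- function(counts) structure(
    list(timepoint = NA, counts = counts, n_nonrepeat = 0L,
         n_discarded = 0L, n_total = sum(counts)),
    class = "repeat_class_counts")
  t0 <- mk(c(Alu = 145L, L1 = 855L))
  t1 <- mk(c(Alu = 290L, L1 = 710L))
  en <- relative_enrichment(t1, t0)
  expect_equal(unname(en["Alu"]), 2.0)
  expect_equal(as.numeric(relative_enrichment(t0, t0)), c(1, 1))

  # zero-baseline class is missing with a reason
  t2 <- mk(c(Alu = 100L, SAT = 5L))
  en2 <- relative_enrichment(t2, mk(c(Alu = 100L)), classes = c("Alu", "SAT"))
  expect_true(is.na(en2["SAT"]))
  expect_equal(unname(attr(en2, "reason")["SAT"]), "zero_baseline")

  # library-size invariance: scaling all baseline counts cancels
  en3 <- relative_enrichment(t1, mk(c(Alu = 1450L, L1 = 8550L)))
  expect_equal(en3, en)
})

test_that("planted decay shows up as a halved enrichment ratio", {
  sim0 <- simulate_reads(n_reads = 8000,
                         proportions = c(Alu = 0.4, LINE = 0.3, SAT = 0.2,
                                         LTR = 0.1), seed = 30)
  sim1 <- simulate_reads(n_reads = 8000,
                         proportions = c(Alu = 0.2, LINE = 0.4, SAT = 0.28,
                                         LTR = 0.12), seed = 31)
  cc0 <- count_repeat_classes(classify_reads(sim0$placements,
                                             sim0$annotations), "0h")
  cc1 <- count_repeat_classes(classify_reads(sim1$placements,
                                             sim1$annotations), "24h")
  en <- relative_enrichment(cc1, cc0)
  # planted Alu fraction halves; multinomial noise at n ~ 7000 is ~ 2%
  expect_lt(abs(en[["Alu"]] - 0.5), 0.05)
})
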