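# Exclusion filter, frequency tiering, deleteriousness predicate and
# truncation arithmetic.

mk <- function(func_class = "nonsynonymous_snv", freq_kg = NA, freq_evs = NA,
               sift = NA, polyphen = NA, segdup = FALSE, min_depth = 30,
               pos = 100) {
  variant_table(chrom = "chr1", pos = pos, ref = "A", alt = "G", gene = "G1",
                func_class = func_class, carriers = "p1", freq_kg = freq_kg,
                freq_evs = freq_evs, sift = sift, polyphen = polyphen,
                segdup = segdup, min_depth = min_depth)
}

test_that("exclusion filter drops non-coding, segdup and low-depth calls with per-rule counts", {
  v <- rbind(mk("intronic"), mk("nonsynonymous_snv"))
  qc <- qc_filter(v)
  expect_equal(nrow(qc$retained), 1)
  expect_equal(unname(qc$excluded["class"]), 1L)

  expect_equal(nrow(qc_filter(mk(segdup = TRUE))$retained), 0)
  expect_equal(nrow(qc_filter(mk(min_depth = 9))$retained), 0)
  expect_equal(nrow(qc_filter(mk(min_depth = 10))$retained), 1)

  # known composition: counts equal a direct re-count by predicate
  set.seed(5)
  classes <- sample(func_classes(), 100, replace = TRUE)
  v <- do.call(rbind, lapply(seq_along(classes), function(i) {
    mk(classes[i], segdup = runif(1) < 0.2, min_depth = sample(5:40, 1),
       pos = i)
  }))
  qc <- qc_filter(v)
  coding <- c("nonsynonymous_snv", "stopgain", "stoploss", "splice",
              "frameshift_ins", "frameshift_del", "nonframeshift_indel")
  exp_class <- sum(!v$func_class %in% coding)
  exp_segdup <- sum(v$func_class %in% coding & v$segdup)
  exp_depth <- sum(v$func_class %in% coding & !v$segdup & v$min_depth < 10)
  expect_equal(unname(qc$excluded), c(exp_class, exp_segdup, exp_depth))
  expect_equal(nrow(qc$retained), 100 - exp_class - exp_segdup - exp_depth)

  # idempotence
  qc2 <- qc_filter(qc$retained)
  expect_equal(as.data.frame(qc2$retained), as.data.frame(qc$retained))
  expect_equal(sum(qc2$excluded), 0L)

  # empty input allowed
  expect_equal(nrow(qc_filter(v[0, ])$retained), 0)
})

test_that("frequency tiering follows the panel-maximum rule with strict boundaries", {
  expect_equal(frequency_tier(mk(freq_evs = 0.0008)), "rare")
  # dbSNP id without frequency information is still novel
  novel <- mk()
  novel$rsid <- "rs368057493"
  expect_equal(frequency_tier(novel), "novel")
  expect_equal(frequency_tier(mk(freq_kg = 0.03, freq_evs = 0.02)),
               "low_frequency")
  expect_equal(frequency_tier(mk(freq_kg = 0.10)), "common")
  # boundaries: rare is strict <, low-frequency inclusive at both ends
  expect_equal(frequency_tier(mk(freq_kg = 0.01)), "low_frequency")
  expect_equal(frequency_tier(mk(freq_kg = 0.01 - 1e-9)), "rare")
  expect_equal(frequency_tier(mk(freq_kg = 0.05)), "low_frequency")
  expect_equal(frequency_tier(mk(freq_kg = 0.05 + 1e-9)), "common")
  bad <- mk()
  bad$freq_kg <- 1.2
  expect_error(frequency_tier(bad), "outside")
})

test_that("tiering is a total function over random valid inputs", {
  set.seed(11)
  for (rep in 1:200) {
    v <- mk(freq_kg = if (runif(1) < 0.4) NA else runif(1),
            freq_evs = if (runif(1) < 0.4) NA else runif(1))
    tier <- frequency_tier(v)
    expect_true(tier %in% c("novel", "rare", "low_frequency", "common"))
    # exactly one tier: definition check against first principles
    f <- suppressWarnings(max(v$freq_kg, v$freq_evs, na.rm = TRUE))
    expected <- if (is.na(v$freq_kg) && is.na(v$freq_evs)) "novel"
      else if (f < 0.01) "rare"
      else if (f <= 0.05) "low_frequency"
      else "common"
    expect_equal(tier, expected)
  }
})

test_that("deleteriousness predicate applies score cuts and the LoF exemption", {
  expect_true(is_deleterious(mk(sift = 0.00, polyphen = 0.91)))
  expect_false(is_deleterious(mk(sift = 0.59, polyphen = 0.00)))
  expect_true(is_deleterious(mk(sift = 0.05, polyphen = 0.10)))  # boundary
  expect_false(is_deleterious(mk()))  # both scores absent, nonsynonymous
  # truncating classes are deleterious regardless of scores by default
  expect_true(is_deleterious(mk("stopgain", sift = 1.00)))
  cfg_strict <- filter_config(stopgain_exempt_from_scores = FALSE)
  expect_false(is_deleterious(mk("stopgain", sift = 1.00), cfg_strict))
})

test_that("deleteriousness is monotone in the scores", {
  set.seed(3)
  for (rep in 1:100) {
    s <- runif(1); p <- runif(1)
    base <- is_deleterious(mk(sift = s, polyphen = p))
    if (base) {
      # lowering sift or raising polyphen never flips true -> false
      expect_true(is_deleterious(mk(sift = s * runif(1), polyphen = p)))
      expect_true(is_deleterious(mk(sift = s,
                                    polyphen = p + (1 - p) * runif(1))))
    }
  }
})

test_that("truncation fraction matches direct arithmetic", {
  expect_equal(truncation_fraction(1, 100), 100.0)
  # oracle: 100 * (174 - 5 + 1) / 174 = 97.701...
  expect_equal(truncation_fraction(5, 174), round(100 * 170 / 174, 1))
  expect_equal(truncation_fraction(5, 174), 97.7)
  expect_equal(truncation_fraction(50, 50), 2.0)
  expect_error(truncation_fraction(51, 50), "exceeds")
  expect_error(truncation_fraction(0, 50), ">= 1")
})
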