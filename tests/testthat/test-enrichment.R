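# Hypergeometric upper tail, over-representation rows and frequency strata.

test_that("hypergeometric upper tail matches exhaustive enumeration and phyper", {
  # 5/210 by direct enumeration of all C(10,4) draws
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_upper_tail(6, 6, 6, 6), 1.0)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "bounds")
  expect_error(hypergeom_upper_tail(2, 5, 4, 3), "bounds")

  # small-universe sweep against the enumeration oracle
  for (N in c(6, 8)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   oracle_hypergeom_tail(k, K, n, N), tolerance = 1e-12)
    }
  }
  # independent library cross-check on larger parameters
  set.seed(8)
  for (rep in 1:50) {
    N <- sample(50:5000, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("enrichment rows carry exact expected counts and BH-monotone fdr", {
  # the printed worked example: set of 27 genes, list fraction 0.13444
  expect_equal(round(27 * 0.13444, 2), 3.63)
  N <- 5000; n <- round(0.13444 * N)
  background <- sprintf("B%04d", 1:N)
  gene_list <- background[1:n]
  sets <- gene_set_collection(list(
    S1 = background[c(1:12, 4901:4915)],      # 12 hits in a 27-gene set
    S2 = background[4001:4100],               # no hits, large set
    S3 = background[1:5]                      # small set, filtered by size
  ))
  rows <- enrich(gene_list, background, sets, filter = FALSE)
  s1 <- rows[rows$set_id == "S1", ]
  expect_equal(s1$count, 12)
  expect_equal(s1$set_size, 27)
  expect_equal(s1$exp_count, 27 * n / N)
  expect_equal(s1$p, hypergeom_upper_tail(12, 27, n, N))
  # exp_count linearity: doubling the list doubles exp_count
  rows2 <- enrich(background[1:(2 * n)], background, sets, filter = FALSE)
  expect_equal(rows2$exp_count[rows2$set_id == "S1"], 2 * s1$exp_count)
  # BH fdr is monotone non-decreasing along p-sorted rows
  expect_true(all(diff(rows$fdr) >= -1e-12))
  # filtering applies p, fdr and size rules
  kept <- enrich(gene_list, background, sets)
  expect_true(all(kept$p < 0.01 & kept$fdr < 0.01 & kept$set_size > 10))
  expect_false("S3" %in% kept$set_id)
  expect_error(enrich("A", character(0), sets), "background")
  expect_error(enrich("ZZZ", background, sets), "outside")
})

test_that("a maximally enriched set attains the minimal p; null lists are calibrated", {
  background <- sprintf("B%03d", 1:200)
  gene_list <- background[1:20]
  sets <- gene_set_collection(list(
    EXACT = gene_list, OTHER1 = background[51:90], OTHER2 = background[91:130]
  ))
  rows <- enrich(gene_list, background, sets, filter = FALSE)
  expect_equal(rows$set_id[1], "EXACT")
  expect_true(rows$p[1] < min(rows$p[-1]))

  # under random gene lists, P(p < 0.05) is near 0.05
  set.seed(12)
  sets_null <- gene_set_collection(setNames(
    lapply(1:20, function(i) sample(background, 30)), sprintf("N%02d", 1:20)))
  hits <- replicate(60, {
    gl <- sample(background, 25)
    mean(enrich(gl, background, sets_null, filter = FALSE)$p < 0.05)
  })
  # discrete hypergeometric p-values are conservative: the rejection rate is
  # bounded by the nominal level (plus Monte-Carlo error) but may sit below it
  expect_lt(mean(hits), 0.08)
  expect_gt(mean(hits), 0)
})

test_that("frequency strata follow the relaxed filter and panel rules", {
  strata <- stratify_by_frequency(table2_variants())
  expect_setequal(strata$novel,
                  c("CNTNAP2", "ERC1", "GRIN2B", "SEMA6D", "GRIN2A"))
  mkv <- function(freq_kg = NA, freq_evs = NA, sift = NA,
                  func_class = "nonsynonymous_snv", gene = "GX") {
    variant_table(chrom = "chr1", pos = 1, ref = "A", alt = "G", gene = gene,
                  func_class = func_class, carriers = "p1",
                  freq_kg = freq_kg, freq_evs = freq_evs, sift = sift)
  }
  expect_equal(stratify_by_frequency(mkv(freq_kg = 0.03))$low_frequency, "GX")
  # predictions are ignored by the relaxed filter
  expect_equal(stratify_by_frequency(mkv(freq_kg = 0.002, sift = 0.9))$rare_reported,
               "GX")
  # above 5% in the reference panel: excluded entirely
  s <- stratify_by_frequency(mkv(freq_kg = 0.10))
  expect_equal(lengths(s), c(novel = 0L, rare_reported = 0L,
                             low_frequency = 0L))
  # absent from the panel but reported in the other: fits no stratum
  s2 <- stratify_by_frequency(mkv(freq_evs = 0.002))
  expect_equal(sum(lengths(s2)), 0L)
  # splice variants are outside the relaxed class set
  s3 <- stratify_by_frequency(mkv(freq_kg = 0.002, func_class = "splice"))
  expect_equal(sum(lengths(s3)), 0L)
})
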