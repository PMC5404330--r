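# Stop-gain screen, compound-het detection with proximity exclusion, and
# multiple-hit pooling.

test_that("the worked-example stop-gain screen retains all 7 records with truncation annotation", {
  sg <- stopgain_screen(table3_variants(),
                        protein_info = table3_protein_lengths())
  expect_equal(nrow(sg), 7)
  expect_true(all(sg$tier == "rare"))
  expect_equal(sg$pct_protein_missing[sg$gene == "OXR1"], 97.7)
  expect_equal(sg$pct_protein_missing[sg$gene == "MUC6"], 71.2)
  # every panel frequency below 0.25%
  expect_lt(max(c(sg$freq_kg, sg$freq_evs), na.rm = TRUE), 0.0025)
})

test_that("stop-gain screen excludes common tiers and non-truncating classes", {
  v <- table3_variants()
  v$freq_kg[1] <- 0.02  # push one record into the low-frequency tier
  expect_equal(nrow(stopgain_screen(v)), 6)
  nonsyn <- table2_variants()
  expect_equal(nrow(stopgain_screen(nonsyn)), 0)
})

test_that("planted stop-gains are recovered exactly among background variants", {
  co <- simulate_cohort(sim_config(n_families = 15, n_genes = 120,
                                   plant_candidate = 0, plant_stopgain = 3,
                                   plant_comphet = 0, plant_denovo = 0,
                                   plant_pathway = list(set_id = NULL,
                                                        carrier_fraction = 0),
                                   n_pathways = 4, pathway_size = 10,
                                   seed = 33))
  sg <- stopgain_screen(qc_filter(co$variants)$retained)
  truth <- co$truth[co$truth$category == "stopgain", ]
  expect_equal(sort(variant_key(sg)),
               sort(variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)))
})

test_that("the worked-example comphet grouping finds 11 genes", {
  cc <- comphet_candidates(table4_variants())
  genes <- vapply(cc, `[[`, "", "gene")
  expect_equal(length(unique(genes)), 11)
  expect_setequal(unique(genes),
                  c("SCN9A", "BIRC6", "FLNB", "OR52B2", "FAT3", "KMT2D",
                    "MYO16", "KIAA0586", "STARD9", "PALB2", "MYO19"))
  # every group member re-passes the qualifying predicates
  for (g in cc) {
    expect_true(all(frequency_tier(g$variants) %in% c("novel", "rare")))
    expect_true(all(is_deleterious(g$variants)))
    expect_true(all(g$phase == "unknown"))
    expect_gte(nrow(g$variants), 2)
  }
  # multi-carrier rows produce one group per carrier proband
  birc6 <- cc[vapply(cc, `[[`, "", "gene") == "BIRC6"]
  expect_setequal(vapply(birc6, `[[`, "", "proband"), c("26", "42"))
})

test_that("proximity exclusion removes both members of close pairs", {
  v <- variant_table(
    chrom = "chr5", pos = c(1000, 1005), ref = c("A", "C"), alt = c("G", "T"),
    gene = "GX", func_class = "nonsynonymous_snv", carriers = "p1",
    freq_kg = 0.001, sift = 0.01
  )
  expect_length(comphet_candidates(v), 0)
  # a third distant qualifying variant is not enough once the close pair is gone
  v3 <- rbind(v, variant_table(
    chrom = "chr5", pos = 9000, ref = "A", alt = "G", gene = "GX",
    func_class = "nonsynonymous_snv", carriers = "p1", freq_kg = 0.001,
    sift = 0.01
  ))
  expect_length(comphet_candidates(v3), 0)
  # boundary: exactly proximity_bp apart is still excluded; one bp more is kept
  v$pos <- c(1000, 1010)
  expect_length(comphet_candidates(v), 0)
  v$pos <- c(1000, 1011)
  expect_length(comphet_candidates(v), 1)
})

test_that("comphet grouping equals the brute-force oracle and ignores row order", {
  set.seed(17)
  for (rep in 1:10) {
    v <- random_cohort(n_variants = 120, n_probands = 12, n_genes = 20)
    got <- comphet_canonical(comphet_candidates(v))
    want <- oracle_comphet(v)
    expect_equal(got, want)
    # row-order invariance
    shuffled <- v[sample(nrow(v)), ]
    expect_equal(comphet_canonical(comphet_candidates(shuffled)), want)
  }
})

test_that("multiple-hit pooling spans categories and distinct variants", {
  # proband with one novel candidate-gene variant and one rare stop-gain
  cand <- variant_table(chrom = "chr15", pos = 48063365, ref = "C", alt = "G",
                        gene = "SEMA6D", func_class = "nonsynonymous_snv",
                        carriers = "30")
  cand$tier <- "novel"
  sg <- variant_table(chrom = "chr3", pos = 63466576, ref = "C", alt = "A",
                      gene = "SYNPR", func_class = "stopgain",
                      carriers = "30", freq_evs = 1e-4, sift = 1)
  sg$tier <- "rare"
  mh <- multihit_probands(cand, sg, structure(list(), class = "comphet_set"))
  expect_equal(unique(mh$proband), "30")
  expect_setequal(mh$category, c("candidate_gene", "stopgain"))

  # a single hit is not reported
  mh1 <- multihit_probands(cand, sg[0, ], structure(list(), class = "comphet_set"))
  expect_equal(nrow(mh1), 0)

  # a proband whose only finding is one comphet pair is reported once,
  # category comphet_gene
  cc <- comphet_candidates(variant_table(
    chrom = "chr5", pos = c(1000, 2000), ref = "A", alt = "G", gene = "GX",
    func_class = "nonsynonymous_snv", carriers = "p9", freq_kg = 0.001,
    sift = 0.01
  ))
  mh2 <- multihit_probands(cand[0, ], sg[0, ], cc)
  expect_equal(unique(mh2$proband), "p9")
  expect_equal(unique(mh2$category), "comphet_gene")
  expect_equal(nrow(mh2), 2)  # the two pair members

  # superset property: probands appearing in >= 2 screens are always reported
  mh3 <- multihit_probands(cand, sg, cc)
  expect_true(all(c("30", "p9") %in% mh3$proband))
})

test_that("rare homozygous disruptive genotypes are reported separately", {
  v <- variant_table(chrom = "chr2", pos = 500, ref = "A", alt = "G",
                     gene = "GH", func_class = "nonsynonymous_snv",
                     carriers = "p1", freq_kg = 0.001, sift = 0.01)
  gt <- data.frame(key = "chr2:500:A:G", iid = c("p1", "p2"),
                   gt = c("hom_alt", "het"), stringsAsFactors = FALSE)
  hom <- hom_alt_disruptive(v, gt)
  expect_equal(hom$iid, "p1")
  expect_equal(hom$gene, "GH")
})
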