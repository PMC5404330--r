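# Synthetic cohort generator: determinism, Mendelian validity, spectrum
# fidelity, affection round-trip and planted-signal bookkeeping.

test_that("identical seeds give byte-identical output files", {
  cfg <- sim_config(n_families = 6, n_genes = 40, seed = 123,
                    plant_comphet = 1, plant_denovo = 1, plant_candidate = 1,
                    plant_stopgain = 1, n_pathways = 3, pathway_size = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the cohort
  simulate_cohort(sim_config(n_families = 6, n_genes = 40, seed = 124,
                             plant_comphet = 1, plant_denovo = 1,
                             plant_candidate = 1, plant_stopgain = 1,
                             n_pathways = 3, pathway_size = 8), dir = d2)
  expect_false(identical(readLines(file.path(d1, "cohort_variants.tsv")),
                         readLines(file.path(d2, "cohort_variants.tsv"))))
})

test_that("emitted files parse with the package readers and agree with the objects", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_families = 5, n_genes = 30, seed = 2,
                                   n_pathways = 3, pathway_size = 8,
                                   plant_comphet = 1, plant_denovo = 1,
                                   plant_candidate = 1, plant_stopgain = 1),
                        dir = d)
  v <- read_variant_table(file.path(d, "cohort_variants.tsv"))
  expect_equal(nrow(v), nrow(co$variants))
  expect_equal(v$pos, co$variants$pos)
  ped <- read_ped(file.path(d, "cohort.ped"))
  expect_equal(sort(ped$iid), sort(co$ped$iid))
  expect_equal(ped$affected[match(co$ped$iid, ped$iid)], co$ped$affected)
  gmt <- read_gmt(file.path(d, "pathways.gmt"))
  expect_equal(gmt$sets, co$pathways$sets)
  # every planted record exists in the emitted variant table
  truth <- co$truth
  expect_true(all(variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
                  %in% variant_key(v)))
})

test_that("simulated cohorts are Mendelian-consistent and every variant has a proband carrier", {
  co <- simulate_cohort(sim_config(n_families = 10, n_genes = 60, seed = 31,
                                   n_pathways = 4, pathway_size = 10))
  expect_equal(nrow(mendelian_audit(co$ped, co$genotypes)), 0)
  expect_true(all(!is.na(co$variants$carriers) & nzchar(co$variants$carriers)))
  # carrier annotations match the genotype table
  probands <- co$ped$iid[co$ped$role == "proband"]
  long <- expand_carriers(co$variants)
  for (i in sample(nrow(long), 40)) {
    gt <- co$genotypes$gt[co$genotypes$key == long$key[i] &
                            co$genotypes$iid == long$proband[i]]
    expect_true(length(gt) == 1 && gt %in% c("het", "hom_alt"))
  }
})

test_that("the tier spectrum converges to the configured mixture", {
  cfg <- sim_config(n_families = 3, sibs_min = 1, sibs_max = 1,
                    n_genes = 2600, variants_per_gene = 4,
                    plant_candidate = 0, plant_stopgain = 0,
                    plant_comphet = 0, plant_denovo = 0,
                    plant_pathway = list(set_id = NULL, carrier_fraction = 0),
                    n_pathways = 2, pathway_size = 5, seed = 77)
  co <- simulate_cohort(cfg)
  tiers <- frequency_tier(co$variants)
  expect_gte(length(tiers), 1e4)
  counts <- table(factor(tiers, levels = names(cfg$tier_mixture)))
  gof <- stats::chisq.test(counts, p = cfg$tier_mixture)
  expect_gt(gof$p.value, 0.01)
})

test_that("affection status round-trips through the emitted scores", {
  co <- simulate_cohort(sim_config(n_families = 12, n_genes = 40, seed = 8,
                                   n_pathways = 3, pathway_size = 8))
  kids <- co$ped[co$ped$role != "parent", ]
  expect_equal(kids$affected, affection_status(kids$els, kids$rls))
  expect_true(all(kids$affected %in% c("affected", "unaffected")))
  # probands are ascertained affected
  expect_true(all(co$ped$affected[co$ped$role == "proband"] == "affected"))
  # parents are never classified from scores
  expect_true(all(co$ped$affected[co$ped$role == "parent"] == "unknown"))
})

test_that("plant capacity violations error; empty plants yield clean screens", {
  expect_error(sim_config(n_families = 3, plant_comphet = 2, plant_denovo = 1,
                          plant_candidate = 1, plant_stopgain = 1),
               "exceed")
  co <- simulate_cohort(sim_config(n_families = 8, n_genes = 60,
                                   plant_candidate = 0, plant_stopgain = 0,
                                   plant_comphet = 0, plant_denovo = 0,
                                   plant_pathway = list(set_id = NULL,
                                                        carrier_fraction = 0),
                                   n_pathways = 3, pathway_size = 8,
                                   seed = 55))
  v <- qc_filter(co$variants)$retained
  expect_equal(nrow(screen_candidates(v)$shortlist), 0)
  expect_equal(nrow(stopgain_screen(v)), 0)
  expect_length(comphet_candidates(v), 0)
  expect_equal(nrow(co$truth), 0)
})
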