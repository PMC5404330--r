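# Affection derivation, transmission origins, comphet phasing,
# co-segregation and the Mendelian audit.

test_that("affection status applies the 1.5 SD cutoff strictly", {
  expect_equal(affection_status(65.9, NA), "affected")
  expect_equal(affection_status(100, 100), "unaffected")
  expect_equal(affection_status(77.5, 100), "unaffected")  # boundary strict
  expect_equal(affection_status(77.4, 100), "affected")
  expect_equal(affection_status(100, 70), "affected")  # either score suffices
  expect_equal(affection_status(NA, NA), "unknown")
  expect_error(affection_status(-5, 100), "negative")
})

test_that("transmission origins cover de novo, parental and inferred cases", {
  expect_equal(transmission_origin("het", "hom_ref", "hom_ref"), "de_novo")
  expect_equal(transmission_origin("het", "hom_ref", "missing"),
               "inferred_maternal")
  expect_equal(transmission_origin("het", "missing", "hom_ref"),
               "inferred_paternal")
  expect_equal(transmission_origin("het", "het", "het"), "unknown")
  expect_equal(transmission_origin("het", "het", "hom_ref"), "paternal")
  expect_equal(transmission_origin("het", "hom_ref", "het"), "maternal")
  expect_equal(transmission_origin("hom_ref", "het", "het"), "unknown")
  expect_error(transmission_origin("missing", "het", "het"), "missing")
})

test_that("transmission_check reads family genotypes and errors on ungenotyped probands", {
  fam <- mk_family("F1", n_sibs = 1, gts = list(
    "chr8:107738486:G:A" = c(F1_P = "het", F1_M = "hom_ref")
  ))
  # father absent from the genotype table entirely: treated as hom_ref carrier
  # convention would be wrong for inference, so pass explicit missing father
  fam$genotypes <- rbind(fam$genotypes,
                         data.frame(key = "chr8:107738486:G:A", iid = "F1_D",
                                    gt = "missing"))
  expect_equal(transmission_check("chr8:107738486:G:A", fam$ped,
                                  fam$genotypes), "inferred_paternal")
  expect_error(transmission_check("chr9:1:A:G", fam$ped, fam$genotypes),
               "missing")
})

test_that("comphet phasing resolves trans, cis and unknown configurations", {
  v <- variant_table(chrom = "chr5", pos = c(1000, 2000), ref = "A",
                     alt = "G", gene = "GX", func_class = "nonsynonymous_snv",
                     carriers = "F1_P", freq_kg = 0.001, sift = 0.01)
  cand <- comphet_candidates(v)[[1]]
  trans_fam <- mk_family("F1", gts = list(
    "chr5:1000:A:G" = c(F1_P = "het", F1_D = "het", F1_M = "hom_ref"),
    "chr5:2000:A:G" = c(F1_P = "het", F1_D = "hom_ref", F1_M = "het")
  ))
  expect_equal(phase_comphet(cand, trans_fam$ped, trans_fam$genotypes)$phase,
               "trans")
  cis_fam <- mk_family("F1", gts = list(
    "chr5:1000:A:G" = c(F1_P = "het", F1_D = "hom_ref", F1_M = "het"),
    "chr5:2000:A:G" = c(F1_P = "het", F1_D = "hom_ref", F1_M = "het")
  ))
  expect_equal(phase_comphet(cand, cis_fam$ped, cis_fam$genotypes)$phase,
               "cis")
  unk_fam <- mk_family("F1", gts = list(
    "chr5:1000:A:G" = c(F1_P = "het", F1_D = "hom_ref", F1_M = "het"),
    "chr5:2000:A:G" = c(F1_P = "het", F1_D = "het", F1_M = "het")
  ))
  expect_equal(phase_comphet(cand, unk_fam$ped, unk_fam$genotypes)$phase,
               "unknown")
})

test_that("phasing recovers trans with zero error on simulated families", {
  co <- simulate_cohort(sim_config(n_families = 10, n_genes = 60,
                                   plant_candidate = 0, plant_stopgain = 0,
                                   plant_comphet = 4, plant_denovo = 0,
                                   plant_pathway = list(set_id = NULL,
                                                        carrier_fraction = 0),
                                   n_pathways = 4, pathway_size = 10,
                                   seed = 99))
  cc <- comphet_candidates(qc_filter(co$variants)$retained)
  expect_length(cc, 4)
  phased <- lapply(cc, phase_comphet, ped = co$ped, genotypes = co$genotypes)
  expect_true(all(vapply(phased, `[[`, "", "phase") == "trans"))
})

test_that("co-segregation verdicts follow the carrier/affection contingency", {
  key <- "chr8:107738486:G:A"
  # three affected carrier children, no unaffected
  f1 <- mk_family("F1", n_sibs = 2, els = c(NA, NA, 60, 70, 75),
                  gts = setNames(list(c(F1_P = "het", F1_S1 = "het",
                                        F1_S2 = "het")), key))
  expect_equal(cosegregation(key, f1$ped, f1$genotypes)$verdict,
               "co_segregates")
  # one affected carrier + one unaffected carrier -> partial
  f2 <- mk_family("F2", n_sibs = 1, els = c(NA, NA, 60, 100),
                  gts = setNames(list(c(F2_P = "het", F2_S1 = "het")), key))
  expect_equal(cosegregation(key, f2$ped, f2$genotypes)$verdict, "partial")
  # affected non-carrier + unaffected carrier -> contradicts
  f3 <- mk_family("F3", n_sibs = 1, els = c(NA, NA, 60, 100),
                  gts = setNames(list(c(F3_S1 = "het")), key))
  expect_equal(cosegregation(key, f3$ped, f3$genotypes)$verdict, "contradicts")
  # children with unknown affection are excluded; < 2 informative children
  f4 <- mk_family("F4", n_sibs = 1, els = c(NA, NA, 60, NA),
                  rls = c(NA, NA, 60, NA),
                  gts = setNames(list(c(F4_P = "het", F4_S1 = "het")), key))
  expect_equal(cosegregation(key, f4$ped, f4$genotypes)$verdict,
               "uninformative")
  # symmetric under relabeling of children
  f1b <- f1
  f1b$ped <- f1$ped[c(1, 2, 5, 4, 3), ]
  expect_equal(cosegregation(key, f1b$ped, f1b$genotypes)$verdict,
               "co_segregates")
})

test_that("the Mendelian audit flags impossible child genotypes only", {
  key <- "chr1:100:A:G"
  bad <- mk_family("F1", n_sibs = 0, gts = setNames(
    list(c(F1_P = "hom_alt", F1_D = "hom_ref", F1_M = "hom_ref")), key))
  aud <- mendelian_audit(bad$ped, bad$genotypes)
  expect_equal(nrow(aud), 1)
  expect_match(aud$problem, "hom_alt child")
  # a de novo het is not an inconsistency
  dn <- mk_family("F1", n_sibs = 0, gts = setNames(
    list(c(F1_P = "het", F1_D = "hom_ref", F1_M = "hom_ref")), key))
  expect_equal(nrow(mendelian_audit(dn$ped, dn$genotypes)), 0)
  # simulated cohorts are Mendelian-consistent
  co <- simulate_cohort(sim_config(n_families = 8, n_genes = 50, seed = 4,
                                   plant_comphet = 2, plant_denovo = 1,
                                   plant_candidate = 1, plant_stopgain = 1,
                                   n_pathways = 4, pathway_size = 10))
  expect_equal(nrow(mendelian_audit(co$ped, co$genotypes)), 0)
})

test_that("segregation report combines origin and co-segregation per family", {
  key <- "chr8:107738486:G:A"
  fam <- mk_family("F1", n_sibs = 2, els = c(NA, NA, 60, 70, 100),
                   gts = setNames(list(c(F1_P = "het", F1_S1 = "het",
                                         F1_M = "hom_ref", F1_D = "het")),
                                  key))
  v <- variant_table(chrom = "chr8", pos = 107738486, ref = "G", alt = "A",
                     gene = "OXR1", func_class = "stopgain",
                     carriers = "F1_P", freq_kg = 0.0014, sift = 1)
  rep <- segregation_report(v, fam$ped, fam$genotypes)
  expect_equal(rep$origin, "paternal")
  expect_equal(rep$cosegregation, "co_segregates")
  expect_equal(rep$carriers_affected, 2)
  expect_equal(rep$noncarriers_affected, 0)
})
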