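## Seeded generator of synthetic annotated-variant cohorts: nuclear families
## with Mendelian transmission, a four-tier frequency spectrum, benign
## background scores, and planted signals (candidate-gene variants,
## stop-gains, trans compound-het pairs, de novos, an enriched pathway) with
## a truth manifest for recovery testing.

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 43 nuclear families each ascertained
#' through one severely language-impaired proband, with 1-3 genotyped
#' siblings and both parents; a candidate-call frequency spectrum of 48.6%
#' common / 21.6% low-frequency / 16.2% rare / 13.5% novel; and the planted
#' signal set recovered by the pipeline (4 trans compound-het pairs, 3 rare
#' stop-gains, 1 de novo, 1 pathway with a rare-variant excess). Background
#' variants carry benign SIFT/PolyPhen scores; planted variants carry
#' deleterious ones (SIFT below 0.05, PolyPhen above 0.85), so screen
#' recovery against the truth manifest is exact by construction.
#'
#' @param n_families Number of nuclear families (default 43).
#' @param sibs_min,sibs_max Range of siblings per family besides the proband
#'   (default 1-3).
#' @param n_genes Number of background genes (default 300).
#' @param variants_per_gene Poisson mean of background variants per gene
#'   (default 2).
#' @param tier_mixture Named proportions over `common`, `low_frequency`,
#'   `rare`, `novel` (normalized; defaults above).
#' @param class_mixture Named proportions over background functional classes.
#' @param segdup_rate,low_depth_rate Fractions of background variants flagged
#'   as segmental-duplication overlaps / under-covered (exercise the QC
#'   filter; defaults 0.02 each).
#' @param plant_candidate Planted rare/novel candidate-gene variants
#'   (default 2).
#' @param plant_stopgain Planted rare stop-gains (default 3).
#' @param plant_comphet Planted trans compound-het pairs (default 4).
#' @param plant_denovo Planted de novo substitutions (default 1).
#' @param plant_pathway List with `set_id` and `carrier_fraction`: fraction
#'   of probands given one qualifying rare deleterious variant in a gene of
#'   that pathway (default `PW01`, 0.7).
#' @param n_pathways,pathway_size Gene-set collection layout over the
#'   background genes (default 20 sets of 15).
#' @param penetrance Probability that a sibling carrying a family's planted
#'   variant is affected (default 0.9).
#' @param phenocopy Probability that a non-carrier sibling is affected
#'   anyway (default 0.05).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 43L, sibs_min = 1L, sibs_max = 3L,
                       n_genes = 300L, variants_per_gene = 2,
                       tier_mixture = c(common = 0.486, low_frequency = 0.216,
                                        rare = 0.162, novel = 0.135),
                       class_mixture = c(nonsynonymous_snv = 0.80,
                                         synonymous = 0.10,
                                         intronic = 0.05, UTR = 0.05),
                       segdup_rate = 0.02, low_depth_rate = 0.02,
                       plant_candidate = 2L, plant_stopgain = 3L,
                       plant_comphet = 4L, plant_denovo = 1L,
                       plant_pathway = list(set_id = "PW01",
                                            carrier_fraction = 0.7),
                       n_pathways = 20L, pathway_size = 15L,
                       penetrance = 0.9, phenocopy = 0.05,
                       seed = 1L) {
  stopifnot(
    n_families >= 1, sibs_min >= 0, sibs_max >= sibs_min,
    n_genes >= 1, variants_per_gene >= 0,
    all(tier_mixture >= 0), sum(tier_mixture) > 0,
    all(names(tier_mixture) %in% .TIERS), length(tier_mixture) == 4,
    plant_candidate >= 0, plant_stopgain >= 0, plant_comphet >= 0,
    plant_denovo >= 0, penetrance >= 0, penetrance <= 1,
    phenocopy >= 0, phenocopy <= 1
  )
  n_planted_fams <- plant_candidate + plant_stopgain + plant_comphet +
    plant_denovo
  if (n_planted_fams > n_families) {
    stop("planted signal counts exceed the number of families", call. = FALSE)
  }
  if (plant_candidate > length(candidate_genes_default())) {
    stop("more candidate plants than candidate genes", call. = FALSE)
  }
  if (n_pathways * pathway_size > n_genes) {
    stop("pathway layout needs n_pathways * pathway_size <= n_genes",
         call. = FALSE)
  }
  structure(list(
    n_families = as.integer(n_families),
    sibs_min = as.integer(sibs_min), sibs_max = as.integer(sibs_max),
    n_genes = as.integer(n_genes), variants_per_gene = variants_per_gene,
    tier_mixture = tier_mixture / sum(tier_mixture),
    class_mixture = class_mixture / sum(class_mixture),
    segdup_rate = segdup_rate, low_depth_rate = low_depth_rate,
    plant_candidate = as.integer(plant_candidate),
    plant_stopgain = as.integer(plant_stopgain),
    plant_comphet = as.integer(plant_comphet),
    plant_denovo = as.integer(plant_denovo),
    plant_pathway = plant_pathway,
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    penetrance = penetrance, phenocopy = phenocopy,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## tier-specific frequency draw, log-uniform within the tier's bounds
.draw_freq <- function(tier, n = length(tier)) {
  lo <- c(common = 0.051, low_frequency = 0.010, rare = 1e-4, novel = 1)[tier]
  hi <- c(common = 0.50, low_frequency = 0.050, rare = 0.0099, novel = 1)[tier]
  f <- exp(stats::runif(n, log(lo), log(hi)))
  f[tier == "novel"] <- NA_real_
  f
}

.benign_scores <- function(n) {
  ## beta-distributed with all mass on the benign side of the 0.05/0.85 cuts
  list(sift = 0.10 + 0.90 * stats::rbeta(n, 2, 2),
       polyphen = 0.80 * stats::rbeta(n, 1.5, 4))
}
.deleterious_scores <- function(n) {
  list(sift = 0.05 * stats::rbeta(n, 1, 4),
       polyphen = 0.85 + 0.15 * stats::rbeta(n, 4, 1))
}

#' Simulate a synthetic exome-screen cohort
#'
#' Generates nuclear families, background variants with Mendelian
#' transmission from parental genotypes drawn under Hardy-Weinberg at each
#' variant's tier-specific allele frequency (every background variant is
#' ascertained through at least one carrier proband), and the planted signal
#' set described in [sim_config()]. Compound-het pairs are placed in trans
#' (one variant per parental haplotype) more than 10 bp apart; de novos are
#' absent from both parents; affected children receive language scores below
#' the affection cutoff, unaffected above it, so affection status
#' round-trips through score derivation.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `cohort_variants.tsv` (dialect), `cohort.ped`, `cohort_genotypes.tsv`,
#'   `pathways.gmt` and `truth_manifest.tsv`.
#' @return List of class `sim_cohort`: `variants` (a `sli_variants` table),
#'   `genotypes` (long table of non-reference and missing calls), `ped`
#'   (a `sli_ped`), `pathways` (a `gene_set_collection`), `truth` (the
#'   manifest data.frame), `universe` (all genes with variants) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = .GlobalEnv))
  set.seed(cfg$seed)

  nf <- cfg$n_families
  fids <- sprintf("F%02d", seq_len(nf))
  n_sibs <- if (cfg$sibs_max > cfg$sibs_min) {
    sample(cfg$sibs_min:cfg$sibs_max, nf, replace = TRUE)
  } else rep(cfg$sibs_min, nf)

  ## ---- pedigree scaffold -------------------------------------------------
  ped_rows <- lapply(seq_len(nf), function(i) {
    kids <- c(paste0(fids[i], "_P"),
              if (n_sibs[i]) paste0(fids[i], "_S", seq_len(n_sibs[i])))
    data.frame(
      fid = fids[i],
      iid = c(paste0(fids[i], "_D"), paste0(fids[i], "_M"), kids),
      father = c(NA, NA, rep(paste0(fids[i], "_D"), length(kids))),
      mother = c(NA, NA, rep(paste0(fids[i], "_M"), length(kids))),
      sex = c("male", "female",
              sample(c("male", "female"), length(kids), replace = TRUE)),
      role = c("parent", "parent", "proband",
               rep("sibling", length(kids) - 1L)),
      stringsAsFactors = FALSE
    )
  })
  ped <- do.call(rbind, ped_rows)
  probands <- ped$iid[ped$role == "proband"]

  ## ---- background gene / variant layout ----------------------------------
  genes <- sprintf("BG%04d", seq_len(cfg$n_genes))
  gene_chrom <- paste0("chr", rep_len(1:22, cfg$n_genes))
  gene_start <- (seq_len(cfg$n_genes) %/% 22L + 1L) * 1000000L

  n_var_per_gene <- stats::rpois(cfg$n_genes, cfg$variants_per_gene)
  gidx <- rep(seq_len(cfg$n_genes), n_var_per_gene)
  nv <- length(gidx)
  offs <- unlist(lapply(n_var_per_gene[n_var_per_gene > 0], function(k) {
    sort(sample.int(50000L, k))
  }), use.names = FALSE)
  tier <- sample(names(cfg$tier_mixture), nv, replace = TRUE,
                 prob = cfg$tier_mixture)
  f <- .draw_freq(tier)
  cls <- sample(names(cfg$class_mixture), nv, replace = TRUE,
                prob = cfg$class_mixture)
  sc <- .benign_scores(nv)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  bg <- data.frame(
    chrom = gene_chrom[gidx], pos = gene_start[gidx] + offs,
    rsid = ifelse(tier == "novel", NA_character_,
                  sprintf("rs%07d", sample.int(9999999L, nv))),
    ref = ref, alt = alt,
    freq_kg = f, freq_evs = f,
    gene = genes[gidx], func_class = cls,
    coding_change = NA_character_,
    phylop = round(stats::rnorm(nv, 1, 2), 2),
    phastcons = round(stats::rbeta(nv, 2, 2), 3),
    sift = round(sc$sift, 3), polyphen = round(sc$polyphen, 3),
    segdup = stats::runif(nv) < cfg$segdup_rate,
    min_depth = ifelse(stats::runif(nv) < cfg$low_depth_rate,
                       sample(1:9, nv, replace = TRUE),
                       sample(12:90, nv, replace = TRUE)),
    af_eff = ifelse(is.na(f), 5e-4, f),
    stringsAsFactors = FALSE
  )

  ## ---- genotype containers -----------------------------------------------
  gt_key <- list(); gt_iid <- list(); gt_gt <- list()
  add_gt <- function(key, iid, gt) {
    n <- length(gt_key) + 1L
    gt_key[[n]] <<- key; gt_iid[[n]] <<- iid; gt_gt[[n]] <<- gt
  }
  kids_by_fam <- split(ped$iid[ped$role != "parent"],
                       ped$fid[ped$role != "parent"])

  ## background transmission: HWE parents, Mendelian children, forced
  ## ascertainment through the proband of one discovery family
  carriers_of <- character(nv)
  for (j in seq_len(nv)) {
    key <- variant_key(bg$chrom[j], bg$pos[j], bg$ref[j], bg$alt[j])
    af <- bg$af_eff[j]
    fa <- stats::rbinom(nf, 2L, af)
    mo <- stats::rbinom(nf, 2L, af)
    d <- sample.int(nf, 1L)
    fa[d] <- max(fa[d], 1L)
    carr <- character(0)
    for (i in which(fa > 0 | mo > 0)) {
      fam_kids <- kids_by_fam[[fids[i]]]
      f_iid <- paste0(fids[i], "_D"); m_iid <- paste0(fids[i], "_M")
      if (fa[i] > 0) add_gt(key, f_iid, c("het", "hom_alt")[fa[i]])
      if (mo[i] > 0) add_gt(key, m_iid, c("het", "hom_alt")[mo[i]])
      for (kid in fam_kids) {
        pat <- stats::rbinom(1L, 1L, fa[i] / 2)
        mat <- stats::rbinom(1L, 1L, mo[i] / 2)
        if (i == d && kid == paste0(fids[i], "_P")) pat <- 1L  # ascertainment
        ac <- pat + mat
        if (ac > 0) {
          add_gt(key, kid, c("het", "hom_alt")[ac])
          if (kid %in% probands) carr <- c(carr, kid)
        }
      }
    }
    carriers_of[j] <- paste(sort(unique(carr)), collapse = ",")
  }
  bg$carriers <- carriers_of
  bg$af_eff <- NULL

  ## ---- planted signals ----------------------------------------------------
  truth <- list()
  add_truth <- function(category, fid, proband, gene, chrom, pos, ref, alt,
                        origin, note = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      category = category, fid = fid, proband = proband, gene = gene,
      chrom = chrom, pos = pos, ref = ref, alt = alt, origin = origin,
      note = note, stringsAsFactors = FALSE
    )
  }
  planted <- list()
  n_planted_fams <- cfg$plant_candidate + cfg$plant_stopgain +
    cfg$plant_comphet + cfg$plant_denovo
  plant_fams <- if (n_planted_fams) sample(fids, n_planted_fams) else character(0)
  fam_cursor <- 0L
  next_fam <- function() {
    fam_cursor <<- fam_cursor + 1L
    plant_fams[fam_cursor]
  }

  ## transmit one planted heterozygous variant from one parent to the proband
  ## (and Mendelianly to siblings); returns nothing, records genotypes
  plant_transmitted <- function(key, fid, from = c("father", "mother")) {
    from <- match.arg(from)
    par_iid <- paste0(fid, if (from == "father") "_D" else "_M")
    add_gt(key, par_iid, "het")
    add_gt(key, paste0(fid, "_P"), "het")
    sibs <- setdiff(kids_by_fam[[fid]], paste0(fid, "_P"))
    sib_carrier <- character(0)
    for (s in sibs) {
      if (stats::rbinom(1L, 1L, 0.5) == 1L) {
        add_gt(key, s, "het")
        sib_carrier <- c(sib_carrier, s)
      }
    }
    sib_carrier
  }

  mk_planted <- function(chrom, pos, gene, func_class, tier, coding = NA) {
    sc <- .deleterious_scores(1L)
    f <- if (tier == "novel") NA_real_ else
      exp(stats::runif(1, log(1e-4), log(0.0024)))
    ref <- sample(bases, 1L)
    data.frame(
      chrom = chrom, pos = pos,
      rsid = if (tier == "novel") NA_character_ else
        sprintf("rs%07d", sample.int(9999999L, 1L)),
      ref = ref, alt = sample(setdiff(bases, ref), 1L),
      freq_kg = f, freq_evs = f,
      gene = gene, func_class = func_class,
      coding_change = coding,
      phylop = round(stats::runif(1, 2, 6), 2),
      phastcons = round(stats::runif(1, 0.9, 1), 3),
      sift = round(sc$sift, 3), polyphen = round(sc$polyphen, 3),
      segdup = FALSE, min_depth = sample(30:80, 1L),
      carriers = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  sib_carriers <- stats::setNames(vector("list", nf), fids)

  ## candidate-gene plants
  cand_genes <- sample(candidate_genes_default(), cfg$plant_candidate)
  for (i in seq_len(cfg$plant_candidate)) {
    fid <- next_fam()
    tier <- if (i %% 2L) "novel" else "rare"
    row <- mk_planted("chr16", 84400000L + i * 5000L, cand_genes[i],
                      "nonsynonymous_snv", tier)
    key <- variant_key(row$chrom, row$pos, row$ref, row$alt)
    row$carriers <- paste0(fid, "_P")
    from <- if (i %% 2L) "father" else "mother"
    sibs <- plant_transmitted(key, fid, from)
    sib_carriers[[fid]] <- union(sib_carriers[[fid]], sibs)
    add_truth("candidate", fid, paste0(fid, "_P"), row$gene, row$chrom,
              row$pos, row$ref, row$alt,
              if (from == "father") "paternal" else "maternal", tier)
    planted[[length(planted) + 1L]] <- row
  }

  ## stop-gain plants (rare in both panels, below 0.25%)
  for (i in seq_len(cfg$plant_stopgain)) {
    fid <- next_fam()
    gene <- sprintf("SG%02d", i)
    row <- mk_planted("chr20", 5000000L + i * 100000L, gene, "stopgain",
                      "rare")
    key <- variant_key(row$chrom, row$pos, row$ref, row$alt)
    row$carriers <- paste0(fid, "_P")
    sibs <- plant_transmitted(key, fid, "father")
    sib_carriers[[fid]] <- union(sib_carriers[[fid]], sibs)
    add_truth("stopgain", fid, paste0(fid, "_P"), gene, row$chrom, row$pos,
              row$ref, row$alt, "paternal", "rare")
    planted[[length(planted) + 1L]] <- row
  }

  ## trans compound-het plants: one variant per parental haplotype, > 10 bp
  ## apart, both transmitted to the proband
  for (i in seq_len(cfg$plant_comphet)) {
    fid <- next_fam()
    gene <- sprintf("CH%02d", i)
    pos1 <- 8000000L + i * 200000L
    pos2 <- pos1 + 500L
    tiers <- c("rare", "novel")
    r1 <- mk_planted("chr21", pos1, gene, "nonsynonymous_snv", tiers[1])
    r2 <- mk_planted("chr21", pos2, gene, "nonsynonymous_snv", tiers[2])
    k1 <- variant_key(r1$chrom, r1$pos, r1$ref, r1$alt)
    k2 <- variant_key(r2$chrom, r2$pos, r2$ref, r2$alt)
    r1$carriers <- paste0(fid, "_P"); r2$carriers <- paste0(fid, "_P")
    add_gt(k1, paste0(fid, "_D"), "het")
    add_gt(k2, paste0(fid, "_M"), "het")
    add_gt(k1, paste0(fid, "_P"), "het")
    add_gt(k2, paste0(fid, "_P"), "het")
    sibs <- setdiff(kids_by_fam[[fid]], paste0(fid, "_P"))
    for (s in sibs) {
      got <- c(stats::rbinom(1L, 1L, 0.5), stats::rbinom(1L, 1L, 0.5))
      if (got[1]) add_gt(k1, s, "het")
      if (got[2]) add_gt(k2, s, "het")
      if (all(got == 1)) {
        sib_carriers[[fid]] <- union(sib_carriers[[fid]], s)
      }
    }
    add_truth("comphet", fid, paste0(fid, "_P"), gene, r1$chrom, r1$pos,
              r1$ref, r1$alt, "paternal", sprintf("pair%d_trans", i))
    add_truth("comphet", fid, paste0(fid, "_P"), gene, r2$chrom, r2$pos,
              r2$ref, r2$alt, "maternal", sprintf("pair%d_trans", i))
    planted[[length(planted) + 1L]] <- r1
    planted[[length(planted) + 1L]] <- r2
  }

  ## de novo plants: proband het, both parents genotyped hom_ref
  for (i in seq_len(cfg$plant_denovo)) {
    fid <- next_fam()
    gene <- sprintf("DN%02d", i)
    row <- mk_planted("chr22", 3000000L + i * 100000L, gene,
                      "nonsynonymous_snv", "novel")
    key <- variant_key(row$chrom, row$pos, row$ref, row$alt)
    row$carriers <- paste0(fid, "_P")
    add_gt(key, paste0(fid, "_P"), "het")
    add_gt(key, paste0(fid, "_D"), "hom_ref")
    add_gt(key, paste0(fid, "_M"), "hom_ref")
    add_truth("denovo", fid, paste0(fid, "_P"), gene, row$chrom, row$pos,
              row$ref, row$alt, "de_novo", "novel")
    planted[[length(planted) + 1L]] <- row
  }

  ## pathway excess: one qualifying rare deleterious variant per selected
  ## proband, in a gene of the designated pathway
  pw_sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    genes[seq((i - 1L) * cfg$pathway_size + 1L, i * cfg$pathway_size)]
  })
  names(pw_sets) <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  pathways <- gene_set_collection(
    pw_sets, stats::setNames(sprintf("synthetic pathway %d",
                                     seq_len(cfg$n_pathways)),
                             names(pw_sets))
  )
  pw_id <- cfg$plant_pathway$set_id
  if (!is.null(pw_id) && pw_id %in% names(pw_sets) &&
      cfg$plant_pathway$carrier_fraction > 0) {
    n_carr <- round(cfg$plant_pathway$carrier_fraction * nf)
    carr_fams <- sample(fids, n_carr)
    for (idx in seq_along(carr_fams)) {
      fid <- carr_fams[idx]
      gene <- sample(pw_sets[[pw_id]], 1L)
      gi <- match(gene, genes)
      row <- mk_planted(gene_chrom[gi], gene_start[gi] + 60000L + idx,
                        gene, "nonsynonymous_snv", "rare")
      key <- variant_key(row$chrom, row$pos, row$ref, row$alt)
      row$carriers <- paste0(fid, "_P")
      plant_transmitted(key, fid, sample(c("father", "mother"), 1L))
      add_truth("pathway", fid, paste0(fid, "_P"), gene, row$chrom, row$pos,
                row$ref, row$alt, "unknown", pw_id)
      planted[[length(planted) + 1L]] <- row
    }
  }

  ## ---- assemble variant table --------------------------------------------
  all_v <- rbind(bg[, c(names(bg))],
                 if (length(planted)) do.call(rbind, planted))
  all_v$carriers[all_v$carriers == ""] <- NA_character_
  variants <- variant_table(
    chrom = all_v$chrom, pos = all_v$pos, rsid = all_v$rsid,
    ref = all_v$ref, alt = all_v$alt, carriers = all_v$carriers,
    freq_kg = all_v$freq_kg, freq_evs = all_v$freq_evs,
    gene = all_v$gene, func_class = all_v$func_class,
    coding_change = all_v$coding_change, phylop = all_v$phylop,
    phastcons = all_v$phastcons, sift = all_v$sift,
    polyphen = all_v$polyphen, segdup = all_v$segdup,
    min_depth = all_v$min_depth
  )
  variants <- sort_variants(variants)
  rownames(variants) <- NULL
  genotypes <- data.frame(
    key = unlist(gt_key, use.names = FALSE),
    iid = unlist(gt_iid, use.names = FALSE),
    gt = unlist(gt_gt, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  genotypes <- genotypes[order(genotypes$key, genotypes$iid), , drop = FALSE]
  genotypes <- genotypes[!duplicated(genotypes[c("key", "iid")]), , drop = FALSE]
  rownames(genotypes) <- NULL

  ## ---- phenotypes ----------------------------------------------------------
  ## probands are ascertained affected; siblings affected with probability
  ## `penetrance` when carrying a planted family variant, `phenocopy`
  ## otherwise; scores drawn on the implied side of the affection cutoff
  ped$affected <- "unknown"
  is_kid <- ped$role != "parent"
  aff <- logical(nrow(ped))
  for (i in which(is_kid)) {
    if (ped$role[i] == "proband") {
      aff[i] <- TRUE
    } else {
      carrier <- ped$iid[i] %in% sib_carriers[[ped$fid[i]]]
      aff[i] <- stats::runif(1) <
        (if (carrier) cfg$penetrance else cfg$phenocopy)
    }
  }
  n_kid <- sum(is_kid)
  els <- rls <- nwr <- viq <- piq <- rep(NA_real_, nrow(ped))
  draw_score <- function(n, lo, hi) as.numeric(sample(lo:hi, n, replace = TRUE))
  els[is_kid] <- ifelse(aff[is_kid], draw_score(n_kid, 48, 77),
                        draw_score(n_kid, 85, 115))
  rls[is_kid] <- ifelse(aff[is_kid], draw_score(n_kid, 55, 90),
                        draw_score(n_kid, 85, 115))
  nwr[is_kid] <- draw_score(n_kid, 60, 120)
  viq[is_kid] <- ifelse(aff[is_kid], draw_score(n_kid, 70, 100),
                        draw_score(n_kid, 85, 120))
  piq[is_kid] <- draw_score(n_kid, 85, 115)
  ped$els <- els; ped$rls <- rls; ped$nwr <- nwr; ped$viq <- viq; ped$piq <- piq
  ped$affected[is_kid] <- affection_status(ped$els[is_kid], ped$rls[is_kid])
  ped <- ped[, c("fid", "iid", "father", "mother", "sex", "role",
                 "els", "rls", "nwr", "viq", "piq", "affected")]
  class(ped) <- c("sli_ped", "data.frame")

  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    category = character(0), fid = character(0), proband = character(0),
    gene = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), origin = character(0),
    note = character(0), stringsAsFactors = FALSE
  )

  out <- structure(list(
    variants = variants, genotypes = genotypes, ped = ped,
    pathways = pathways, truth = truth,
    universe = sort(unique(variants$gene)), config = cfg
  ), class = "sim_cohort")

  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d families, %d variants in %d genes, %d planted signals\n",
              x$config$n_families, nrow(x$variants),
              length(unique(x$variants$gene)), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    variants = file.path(dir, "cohort_variants.tsv"),
    ped = file.path(dir, "cohort.ped"),
    genotypes = file.path(dir, "cohort_genotypes.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    truth = file.path(dir, "truth_manifest.tsv")
  )
  write_variant_table(cohort$variants, files["variants"])
  ped <- cohort$ped
  sexnum <- c(male = 1L, female = 2L, unknown = 0L)[ped$sex]
  ped_out <- data.frame(
    fid = ped$fid, iid = ped$iid,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = sexnum, pheno = "NA",
    els = ped$els, rls = ped$rls, nwr = ped$nwr, viq = ped$viq, piq = ped$piq,
    stringsAsFactors = FALSE
  )
  utils::write.table(ped_out, files["ped"], sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  utils::write.table(cohort$genotypes, files["genotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$pathways, files["gmt"])
  utils::write.table(cohort$truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}
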