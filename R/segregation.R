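## Affection-status derivation, Mendelian transmission analysis, de novo
## flagging, compound-het phasing and co-segregation within nuclear families.

## CELF-R scores are standardized to mean 100, SD 15; affection is a score
## more than 1.5 SD below the mean, i.e. strictly below 77.5.
.AFFECTION_CUTOFF <- 100 - 1.5 * 15

#' Derive affection status from language scores
#'
#' A child is `affected` when the CELF-R expressive (ELS) or receptive (RLS)
#' language score is more than 1.5 SD below the population mean (strictly
#' below 77.5 on the mean-100/SD-15 scale), `unknown` when both scores are
#' absent, `unaffected` otherwise. A score of exactly 77.5 is unaffected
#' (the threshold is strict).
#'
#' @param els,rls Numeric vectors of standardized scores (`NA` = missing).
#' @return Character vector: `affected`, `unaffected` or `unknown`.
#' @export
affection_status <- function(els, rls = NULL) {
  if (is.null(rls)) rls <- rep(NA_real_, length(els))
  n <- max(length(els), length(rls))
  els <- rep_len(as.numeric(els), n); rls <- rep_len(as.numeric(rls), n)
  if (any(els < 0, na.rm = TRUE) || any(rls < 0, na.rm = TRUE)) {
    stop("negative language score", call. = FALSE)
  }
  out <- rep("unaffected", n)
  out[(!is.na(els) & els < .AFFECTION_CUTOFF) |
        (!is.na(rls) & rls < .AFFECTION_CUTOFF)] <- "affected"
  out[is.na(els) & is.na(rls)] <- "unknown"
  out
}

## Fetch a genotype call from the long genotype table; individuals absent
## from the table are hom_ref (the table stores carrier and missing calls).
.get_gt <- function(genotypes, iid, key) {
  hit <- genotypes$iid == iid & genotypes$key == key
  if (!any(hit)) return("hom_ref")
  genotypes$gt[which(hit)[1]]
}

.carries <- function(gt) gt %in% c("het", "hom_alt")

#' Parental origin of a child's variant allele
#'
#' Classifies the transmission of one variant to one child given parental
#' genotypes: `de_novo` when both parents are genotyped homozygous reference
#' and the child is heterozygous; a definite parental origin when exactly one
#' parent carries the allele; `unknown` when both carry; an inferred origin
#' when one parent is ungenotyped and the genotyped one is homozygous
#' reference (the allele must have come from the missing parent).
#'
#' @param child_gt,father_gt,mother_gt Genotype calls (`hom_ref`, `het`,
#'   `hom_alt`, `missing`).
#' @return One of `de_novo`, `paternal`, `maternal`, `inferred_paternal`,
#'   `inferred_maternal`, `unknown`.
#' @export
transmission_origin <- function(child_gt, father_gt, mother_gt) {
  if (is.na(child_gt) || child_gt == "missing") {
    stop("child genotype missing", call. = FALSE)
  }
  if (!.carries(child_gt)) return("unknown")
  f <- .carries(father_gt); m <- .carries(mother_gt)
  f_miss <- is.na(father_gt) || father_gt == "missing"
  m_miss <- is.na(mother_gt) || mother_gt == "missing"
  if (!f_miss && !m_miss) {
    if (!f && !m) {
      if (child_gt == "het") return("de_novo")
      return("unknown")  # hom-alt child of two non-carriers: audit flags it
    }
    if (f && !m) return("paternal")
    if (!f && m) return("maternal")
    return("unknown")
  }
  if (f_miss && !m_miss && !m) return("inferred_paternal")
  if (m_miss && !f_miss && !f) return("inferred_maternal")
  "unknown"
}

#' Transmission check for a variant within one family
#'
#' Applies [transmission_origin()] to the family's proband using the long
#' genotype table. Errors if the proband is not genotyped for the variant.
#'
#' @param key Variant key (`chrom:pos:ref:alt`, see [variant_key()]).
#' @param ped A `sli_ped` table restricted to (or containing) the family.
#' @param genotypes Long genotype table (`key`, `iid`, `gt`).
#' @param fid Family identifier (defaults to the only family in `ped`).
#' @return Origin string as in [transmission_origin()].
#' @export
transmission_check <- function(key, ped, genotypes, fid = unique(ped$fid)) {
  stopifnot(length(fid) == 1)
  fam <- ped[ped$fid == fid, , drop = FALSE]
  pro <- fam[fam$role == "proband", , drop = FALSE]
  if (nrow(pro) != 1) stop("family must have exactly one proband", call. = FALSE)
  child_gt <- .get_gt(genotypes, pro$iid, key)
  father_gt <- if (is.na(pro$father)) "missing" else .get_gt(genotypes, pro$father, key)
  mother_gt <- if (is.na(pro$mother)) "missing" else .get_gt(genotypes, pro$mother, key)
  ## a proband absent from the genotype table is hom_ref by convention, but a
  ## transmission question only makes sense for an explicitly genotyped child
  if (!any(genotypes$iid == pro$iid & genotypes$key == key) &&
      !.carries(child_gt)) {
    stop("proband genotype missing for variant ", key, call. = FALSE)
  }
  transmission_origin(child_gt, father_gt, mother_gt)
}

#' Phase a compound-heterozygote candidate against parental genotypes
#'
#' Resolves the parental origin of each variant in the group and classifies
#' the pair: `trans` when two variants come from different parents (the true
#' compound-heterozygote configuration), `cis` when from the same parent,
#' `unknown` when origins cannot be resolved. Groups of more than two
#' variants are phased pairwise; the candidate is `trans` if any pair is
#' trans, else `cis` if any pair is cis.
#'
#' @param candidate One element of a `comphet_set` (list with `proband`,
#'   `gene`, `variants`).
#' @param ped A `sli_ped` table containing the proband's family.
#' @param genotypes Long genotype table.
#' @return The candidate with `phase` filled in and an `origins` character
#'   vector (one per variant).
#' @export
phase_comphet <- function(candidate, ped, genotypes) {
  fam_row <- ped[ped$iid == candidate$proband, , drop = FALSE]
  if (nrow(fam_row) != 1) stop("proband not found in pedigree", call. = FALSE)
  fam <- ped[ped$fid == fam_row$fid, , drop = FALSE]
  keys <- variant_key(candidate$variants)
  origins <- vapply(keys, function(k) {
    child_gt <- .get_gt(genotypes, candidate$proband, k)
    father_gt <- if (is.na(fam_row$father)) "missing" else .get_gt(genotypes, fam_row$father, k)
    mother_gt <- if (is.na(fam_row$mother)) "missing" else .get_gt(genotypes, fam_row$mother, k)
    transmission_origin(child_gt, father_gt, mother_gt)
  }, character(1))
  side <- function(o) {
    switch(o,
           paternal = "father", inferred_paternal = "father",
           maternal = "mother", inferred_maternal = "mother",
           NA_character_)
  }
  sides <- vapply(origins, side, character(1))
  phase <- "unknown"
  n <- length(sides)
  pair_phases <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (is.na(sides[i]) || is.na(sides[j])) next
      pair_phases <- c(pair_phases,
                       if (sides[i] != sides[j]) "trans" else "cis")
    }
  }
  if ("trans" %in% pair_phases) phase <- "trans"
  else if ("cis" %in% pair_phases) phase <- "cis"
  candidate$phase <- phase
  candidate$origins <- unname(origins)
  candidate
}

#' Co-segregation of a variant with affection within a nuclear family
#'
#' Compares carrier status with affection across the genotyped, phenotyped
#' children of the family (parents never enter the comparison: the language
#' tests are child-normed; children with `unknown` affection, e.g. a
#' non-CELF diagnosis, are excluded). The verdict is `co_segregates` when
#' every affected child carries the variant and no unaffected child does,
#' `contradicts` when some affected child lacks it and some unaffected child
#' carries it, `uninformative` when fewer than two children are informative,
#' `partial` otherwise.
#'
#' @param key Variant key.
#' @param ped A `sli_ped` table.
#' @param genotypes Long genotype table.
#' @param fid Family identifier (defaults to the only family in `ped`).
#' @return List: `verdict`, `carriers_affected`, `carriers_unaffected`,
#'   `noncarriers_affected`, `noncarriers_unaffected`.
#' @export
cosegregation <- function(key, ped, genotypes, fid = unique(ped$fid)) {
  stopifnot(length(fid) == 1)
  fam <- ped[ped$fid == fid, , drop = FALSE]
  kids <- fam[fam$role %in% c("proband", "sibling"), , drop = FALSE]
  gt <- vapply(kids$iid, .get_gt, character(1), genotypes = genotypes, key = key)
  genotyped <- gt != "missing"
  informative <- genotyped & kids$affected %in% c("affected", "unaffected")
  kids <- kids[informative, , drop = FALSE]
  gt <- gt[informative]
  carrier <- .carries(gt)
  aff <- kids$affected == "affected"
  counts <- list(
    carriers_affected = sum(carrier & aff),
    carriers_unaffected = sum(carrier & !aff),
    noncarriers_affected = sum(!carrier & aff),
    noncarriers_unaffected = sum(!carrier & !aff)
  )
  verdict <- if (nrow(kids) < 2) {
    "uninformative"
  } else if (counts$noncarriers_affected == 0 && counts$carriers_unaffected == 0) {
    "co_segregates"
  } else if (counts$noncarriers_affected > 0 && counts$carriers_unaffected > 0) {
    "contradicts"
  } else {
    "partial"
  }
  c(list(verdict = verdict), counts)
}

#' Per-family segregation report
#'
#' Runs [transmission_check()] and [cosegregation()] for every
#' (variant, carrier family) pair of a variant table and returns the verdict
#' table.
#'
#' @param v Variant table (carriers are proband identifiers).
#' @param ped A `sli_ped` table.
#' @param genotypes Long genotype table.
#' @return data.frame: `fid`, `key`, `gene`, `origin`, `cosegregation`,
#'   `carriers_affected`, `carriers_unaffected`, `noncarriers_affected`.
#' @export
segregation_report <- function(v, ped, genotypes) {
  long <- expand_carriers(v)
  rows <- list()
  for (i in seq_len(nrow(long))) {
    prow <- ped[ped$iid == long$proband[i], , drop = FALSE]
    if (!nrow(prow)) next
    fid <- prow$fid[1]
    origin <- tryCatch(
      transmission_check(long$key[i], ped, genotypes, fid = fid),
      error = function(e) "unknown"
    )
    cs <- cosegregation(long$key[i], ped, genotypes, fid = fid)
    rows[[length(rows) + 1L]] <- data.frame(
      fid = fid, key = long$key[i], gene = long$gene[i], origin = origin,
      cosegregation = cs$verdict,
      carriers_affected = cs$carriers_affected,
      carriers_unaffected = cs$carriers_unaffected,
      noncarriers_affected = cs$noncarriers_affected,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(fid = character(0), key = character(0),
                      gene = character(0), origin = character(0),
                      cosegregation = character(0),
                      carriers_affected = integer(0),
                      carriers_unaffected = integer(0),
                      noncarriers_affected = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Mendelian consistency audit
#'
#' Flags child genotypes impossible under Mendelian transmission from the
#' recorded parental genotypes: a hom-alt child with a genotyped
#' non-carrier parent, or a hom-ref child of a hom-alt parent. A het child
#' of two hom-ref parents is not an inconsistency -- it is exactly the de
#' novo flag.
#'
#' @param ped A `sli_ped` table.
#' @param genotypes Long genotype table.
#' @return data.frame of inconsistencies: `fid`, `iid`, `key`, `problem`
#'   (zero rows when the cohort is Mendelian-consistent).
#' @export
mendelian_audit <- function(ped, genotypes) {
  out <- list()
  keys <- unique(genotypes$key)
  gt_map <- split(genotypes[c("iid", "gt")], genotypes$key)
  kids <- ped[!is.na(ped$father) | !is.na(ped$mother), , drop = FALSE]
  for (key in keys) {
    gmap <- gt_map[[key]]
    lookup <- function(iid) {
      if (is.na(iid)) return("missing")
      hit <- match(iid, gmap$iid)
      if (is.na(hit)) "hom_ref" else gmap$gt[hit]
    }
    for (i in seq_len(nrow(kids))) {
      cg <- lookup(kids$iid[i])
      if (cg == "missing") next
      fg <- lookup(kids$father[i]); mg <- lookup(kids$mother[i])
      problem <- NULL
      if (cg == "hom_alt" &&
          ((fg == "hom_ref") || (mg == "hom_ref"))) {
        problem <- "hom_alt child of a hom_ref parent"
      }
      if (cg == "hom_ref" && (fg == "hom_alt" || mg == "hom_alt")) {
        problem <- "hom_ref child of a hom_alt parent"
      }
      if (!is.null(problem)) {
        out[[length(out) + 1L]] <- data.frame(
          fid = kids$fid[i], iid = kids$iid[i], key = key, problem = problem,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(fid = character(0), iid = character(0),
                      key = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
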