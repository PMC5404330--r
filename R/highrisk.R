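## Stop-gain screen, compound-heterozygote candidate detection with
## proximity exclusion, and multiple-hit proband reports.

#' Rare/novel loss-of-function screen
#'
#' Retains QC-passed variants of truncating class (stop-gain, stop-loss,
#' frameshift insertion/deletion) whose frequency tier is `novel` or `rare`
#' and which pass the deleteriousness predicate (truncating classes are
#' exempt from substitution scores by default, see [filter_config()]).
#' When protein annotation is supplied, each retained record is annotated
#' with the truncated protein fraction.
#'
#' @param v QC-filtered variant table.
#' @param cfg A [filter_config()].
#' @param protein_info Optional data.frame with columns `gene`,
#'   `stop_aa_pos`, `protein_length` used to compute `pct_protein_missing`.
#' @return Variant table of retained records with added columns `tier` and
#'   (when computable) `pct_protein_missing`, sorted by chromosome/position.
#' @export
stopgain_screen <- function(v, cfg = filter_config(), protein_info = NULL) {
  lof <- c("stopgain", "stoploss", "frameshift_ins", "frameshift_del")
  cand <- v[v$func_class %in% lof, , drop = FALSE]
  if (nrow(cand)) {
    tier <- frequency_tier(cand, cfg)
    keep <- tier %in% c("novel", "rare") & is_deleterious(cand, cfg)
    cand <- cand[keep, , drop = FALSE]
    cand$tier <- tier[keep]
  } else {
    cand$tier <- character(0)
  }
  cand$pct_protein_missing <- rep(NA_real_, nrow(cand))
  if (!is.null(protein_info) && nrow(cand)) {
    m <- match(cand$gene, protein_info$gene)
    ok <- !is.na(m)
    if (any(ok)) {
      cand$pct_protein_missing[ok] <- truncation_fraction(
        protein_info$stop_aa_pos[m[ok]], protein_info$protein_length[m[ok]]
      )
    }
  }
  cand <- sort_variants(cand)
  rownames(cand) <- NULL
  cand
}

## Disruptive-variant predicate shared by the comphet and pathway modules:
## protein-disruptive class, novel/rare tier, predicted deleterious, and
## outside segmental duplications.
.qualifies_disruptive <- function(v, cfg) {
  v$func_class %in% .DISRUPTIVE_CLASSES &
    frequency_tier(v, cfg) %in% c("novel", "rare") &
    is_deleterious(v, cfg) &
    !(!is.na(v$segdup) & v$segdup)
}

#' Compound-heterozygote candidate detection
#'
#' Finds probands carrying two or more qualifying variants in a single gene.
#' Qualifying variants are protein-disruptive (nonsynonymous, stop-gain/loss,
#' splice, frameshift), of tier novel or rare, predicted deleterious, and
#' outside segmental duplications. Within each (proband, gene) group, any
#' variant lying within `comphet_proximity_bp` of another is removed (both
#' members of a too-close pair; such clusters are usually alignment
#' artefacts); groups still of size >= 2 are emitted. Phase is `unknown`
#' until resolved against parental genotypes with [phase_comphet()].
#'
#' @param v QC-filtered variant table (carriers comma-separated per row).
#' @param cfg A [filter_config()].
#' @return List of class `comphet_set`; each element has `proband`, `gene`,
#'   `variants` (variant table of the group) and `phase` (`"unknown"`).
#'   Output is independent of input row order.
#' @export
comphet_candidates <- function(v, cfg = filter_config()) {
  out <- list()
  if (nrow(v)) {
    v <- v[.qualifies_disruptive(v, cfg), , drop = FALSE]
    long <- expand_carriers(v)
    if (nrow(long)) {
      long <- long[order(long$proband, long$gene, long$chrom, long$pos,
                         long$ref, long$alt), , drop = FALSE]
      grp <- split(seq_len(nrow(long)),
                   list(long$proband, long$gene), drop = TRUE)
      for (g in grp) {
        rows <- long[g, , drop = FALSE]
        rows <- rows[!duplicated(rows$key), , drop = FALSE]
        if (nrow(rows) < 2) next
        ## proximity exclusion: drop every variant within the window of
        ## another variant of the group on the same chromosome
        too_close <- rep(FALSE, nrow(rows))
        for (i in seq_len(nrow(rows) - 1L)) {
          for (j in seq(i + 1L, nrow(rows))) {
            if (rows$chrom[i] == rows$chrom[j] &&
                abs(rows$pos[i] - rows$pos[j]) <= cfg$comphet_proximity_bp) {
              too_close[i] <- too_close[j] <- TRUE
            }
          }
        }
        rows <- rows[!too_close, , drop = FALSE]
        if (nrow(rows) < 2) next
        out[[length(out) + 1L]] <- list(
          proband = rows$proband[1], gene = rows$gene[1],
          variants = rows[, setdiff(names(rows), "proband"), drop = FALSE],
          phase = "unknown"
        )
      }
    }
  }
  ord <- order(vapply(out, `[[`, "", "proband"), vapply(out, `[[`, "", "gene"))
  structure(out[ord], class = "comphet_set")
}

#' @export
print.comphet_set <- function(x, ...) {
  cat(sprintf("Compound-heterozygote candidates: %d (proband, gene) groups in %d genes\n",
              length(x), length(unique(vapply(x, `[[`, "", "gene")))))
  for (cc in x) {
    cat(sprintf("  proband %s  %s  %d variants  phase %s\n",
                cc$proband, cc$gene, nrow(cc$variants), cc$phase))
  }
  invisible(x)
}

## Flatten a comphet_set to one row per (proband, gene, variant).
comphet_as_table <- function(cc) {
  if (!length(cc)) {
    return(data.frame(proband = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      tier = character(0), phase = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(cc, function(g) {
    data.frame(proband = g$proband, gene = g$gene,
               chrom = g$variants$chrom, pos = g$variants$pos,
               ref = g$variants$ref, alt = g$variants$alt,
               tier = frequency_tier(g$variants),
               phase = g$phase, stringsAsFactors = FALSE)
  }))
}

#' Multiple-hit proband report
#'
#' Pools, per proband, the hits from the three screens -- rare/novel
#' candidate-gene shortlist entries, stop-gain screen entries, and genes with
#' a compound-het candidate group -- and reports probands whose pooled hits
#' span at least two distinct variants. A comphet gene counts once as a hit
#' (category `comphet_gene`) but all its variants count toward the distinct
#' variant total, so a proband whose only finding is one comphet pair is
#' reported.
#'
#' @param candidate_shortlist Shortlist table from [screen_candidates()].
#' @param stopgains Table from [stopgain_screen()].
#' @param comphets A `comphet_set` from [comphet_candidates()].
#' @return data.frame with one row per (proband, category, gene, variant):
#'   columns `proband`, `category` (`candidate_gene`, `stopgain`,
#'   `comphet_gene`), `gene`, `chrom`, `pos`, `ref`, `alt`, restricted to
#'   probands with >= 2 distinct variants pooled across categories.
#' @export
multihit_probands <- function(candidate_shortlist, stopgains, comphets) {
  empty <- data.frame(proband = character(0), category = character(0),
                      gene = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  pool <- empty
  add <- function(v, category) {
    if (is.null(v) || !nrow(v)) return()
    long <- expand_carriers(v)
    if (!nrow(long)) return()
    pool <<- rbind(pool, data.frame(
      proband = long$proband, category = category, gene = long$gene,
      chrom = long$chrom, pos = long$pos, ref = long$ref, alt = long$alt,
      stringsAsFactors = FALSE
    ))
  }
  add(candidate_shortlist, "candidate_gene")
  add(stopgains, "stopgain")
  for (g in comphets) {
    pool <- rbind(pool, data.frame(
      proband = g$proband, category = "comphet_gene", gene = g$gene,
      chrom = g$variants$chrom, pos = g$variants$pos,
      ref = g$variants$ref, alt = g$variants$alt, stringsAsFactors = FALSE
    ))
  }
  if (!nrow(pool)) return(empty)
  pool$key <- variant_key(pool$chrom, pool$pos, pool$ref, pool$alt)
  n_distinct <- vapply(split(pool$key, pool$proband),
                       function(k) length(unique(k)), integer(1))
  keep <- pool$proband %in% names(n_distinct)[n_distinct >= 2L]
  out <- pool[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("proband", "category", "gene", "key")]), , drop = FALSE]
  out <- out[order(out$proband, out$category, out$gene, out$pos), , drop = FALSE]
  out$key <- NULL
  rownames(out) <- NULL
  out
}

#' Rare homozygous disruptive genotypes
#'
#' "Two variant alleles in one gene" is also satisfied by a homozygous rare
#' deleterious genotype; these are reported as a separate category rather
#' than as compound heterozygotes (none occurred in the source cohort).
#'
#' @param v QC-filtered variant table.
#' @param genotypes Long genotype table (`key`, `iid`, `gt`).
#' @param cfg A [filter_config()].
#' @return data.frame with `iid`, `gene`, `chrom`, `pos`, `ref`, `alt` for
#'   each hom-alt call of a qualifying disruptive variant.
#' @export
hom_alt_disruptive <- function(v, genotypes, cfg = filter_config()) {
  v <- v[.qualifies_disruptive(v, cfg), , drop = FALSE]
  v$key <- variant_key(v)
  hom <- genotypes[genotypes$gt == "hom_alt" & genotypes$key %in% v$key, ,
                   drop = FALSE]
  m <- match(hom$key, v$key)
  data.frame(iid = hom$iid, gene = v$gene[m], chrom = v$chrom[m],
             pos = v$pos[m], ref = v$ref[m], alt = v$alt[m],
             stringsAsFactors = FALSE)
}
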