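## Post-annotation exclusion filters, frequency tiering, the SIFT/PolyPhen
## deleteriousness predicate and protein truncation arithmetic.

#' Filtering and classification thresholds
#'
#' Bundles the tunable thresholds of the prioritization pipeline. Defaults
#' follow the study conditions: variants are *rare* below 1% panel frequency
#' and *low-frequency* between 1% and 5%; a substitution is predicted
#' deleterious when SIFT <= 0.05 or PolyPhen-2 >= 0.85; sites covered below
#' depth 10 are excluded; compound-het variant pairs closer than 10 bp are
#' discarded as likely alignment artefacts.
#'
#' @param rare_threshold Fraction; tier boundary for `rare` (strict `<`,
#'   default 0.01). The source wording mixes "<1%" and "<=1%"; the strict
#'   reading is adopted and this argument is the one-line override.
#' @param low_freq_threshold Fraction; upper bound of `low_frequency`
#'   (inclusive, default 0.05).
#' @param sift_max SIFT score at or below which a variant is predicted
#'   deleterious (default 0.05).
#' @param polyphen_min PolyPhen-2 score at or above which a variant is
#'   predicted deleterious (default 0.85).
#' @param min_depth_required Minimum carrier read depth (default 10).
#' @param comphet_proximity_bp Compound-het pairs with positions within this
#'   many base pairs of each other are removed, both members (default 10).
#' @param stopgain_exempt_from_scores Treat loss-of-function classes
#'   (stop-gain/loss, frameshift, splice) as deleterious regardless of
#'   SIFT/PolyPhen (default TRUE; truncating alleles are routinely assigned
#'   uninformative substitution scores).
#' @param tier_panel Which panels feed the tier: `"max"` (default;
#'   conservative maximum over available panels), `"kg"` or `"evs"`.
#' @param depth_semantics `"any_carrier"` (default) keeps a variant when any
#'   carrier reaches the required depth; `"all_carriers"` requires all to.
#'   With per-variant `min_depth` storing the minimum over carriers, the
#'   any-carrier reading excludes only variants whose stored depth proxy is
#'   below threshold.
#' @return A `filter_config` list.
#' @export
filter_config <- function(rare_threshold = 0.01,
                          low_freq_threshold = 0.05,
                          sift_max = 0.05,
                          polyphen_min = 0.85,
                          min_depth_required = 10L,
                          comphet_proximity_bp = 10L,
                          stopgain_exempt_from_scores = TRUE,
                          tier_panel = c("max", "kg", "evs"),
                          depth_semantics = c("any_carrier", "all_carriers")) {
  tier_panel <- match.arg(tier_panel)
  depth_semantics <- match.arg(depth_semantics)
  stopifnot(
    rare_threshold > 0, rare_threshold < low_freq_threshold,
    low_freq_threshold <= 1,
    sift_max >= 0, sift_max <= 1, polyphen_min >= 0, polyphen_min <= 1,
    min_depth_required >= 0, comphet_proximity_bp >= 0
  )
  structure(list(
    rare_threshold = rare_threshold,
    low_freq_threshold = low_freq_threshold,
    sift_max = sift_max,
    polyphen_min = polyphen_min,
    min_depth_required = as.integer(min_depth_required),
    comphet_proximity_bp = as.integer(comphet_proximity_bp),
    stopgain_exempt_from_scores = isTRUE(stopgain_exempt_from_scores),
    tier_panel = tier_panel,
    depth_semantics = depth_semantics
  ), class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Filter configuration:\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Post-annotation exclusion filter
#'
#' Applies the study's exclusion rules in fixed order: (1) functional class
#' must be protein-affecting (nonsynonymous, stop-gain/loss, splice,
#' frameshift or non-frameshift indel -- intergenic, intronic, ncRNA, UTR and
#' synonymous calls are dropped); (2) sites in known segmental duplications
#' are dropped; (3) sites not reaching the required carrier read depth are
#' dropped. Each excluded variant is attributed to the first rule it fails.
#'
#' @param v Variant table.
#' @param cfg A [filter_config()].
#' @return List of class `qc_result`: `retained` (variant table) and
#'   `excluded` (named integer vector with counts for `class`, `segdup`,
#'   `depth`).
#' @export
qc_filter <- function(v, cfg = filter_config()) {
  fail_class <- !v$func_class %in% .CODING_CLASSES
  fail_segdup <- !fail_class & !is.na(v$segdup) & v$segdup
  fail_depth <- !fail_class & !fail_segdup &
    !is.na(v$min_depth) & v$min_depth < cfg$min_depth_required
  keep <- !(fail_class | fail_segdup | fail_depth)
  structure(list(
    retained = v[keep, , drop = FALSE],
    excluded = c(class = sum(fail_class), segdup = sum(fail_segdup),
                 depth = sum(fail_depth))
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC filter: %d retained; excluded %d by class, %d segdup, %d depth\n",
              nrow(x$retained), x$excluded["class"], x$excluded["segdup"],
              x$excluded["depth"]))
  invisible(x)
}

#' Classify variants into reference-panel frequency tiers
#'
#' A variant is `novel` when absent from both reference panels (an existing
#' dbSNP identifier without frequency information does not disqualify it).
#' Otherwise the tier is set by `f`, by default the maximum over available
#' panel frequencies: `rare` for `f < rare_threshold`, `low_frequency` for
#' `rare_threshold <= f <= low_freq_threshold`, `common` above.
#'
#' @param v Variant table (or any data.frame with `freq_kg`, `freq_evs`).
#' @param cfg A [filter_config()].
#' @return Character vector of tiers, one per row: `novel`, `rare`,
#'   `low_frequency` or `common`.
#' @export
frequency_tier <- function(v, cfg = filter_config()) {
  kg <- v$freq_kg; evs <- v$freq_evs
  if (any(!is.na(kg) & (kg < 0 | kg > 1)) || any(!is.na(evs) & (evs < 0 | evs > 1))) {
    stop("panel frequency outside [0, 1]", call. = FALSE)
  }
  f <- switch(cfg$tier_panel,
    max = pmax(kg, evs, na.rm = TRUE),
    kg = kg,
    evs = evs
  )
  ## pmax(NA, NA, na.rm=TRUE) warns and yields -Inf on some paths; normalise
  f[is.na(kg) & is.na(evs)] <- NA_real_
  tier <- rep(NA_character_, nrow(v))
  tier[is.na(kg) & is.na(evs)] <- "novel"
  open <- is.na(tier)
  if (cfg$tier_panel != "max") {
    ## per-panel mode: a variant absent from the chosen panel but present in
    ## the other cannot be tiered by frequency; treat as rare (below
    ## detection in the scoring panel)
    f[open & is.na(f)] <- 0
  }
  tier[open & f < cfg$rare_threshold] <- "rare"
  tier[open & f >= cfg$rare_threshold & f <= cfg$low_freq_threshold] <- "low_frequency"
  tier[open & f > cfg$low_freq_threshold] <- "common"
  tier
}

#' Predicted-deleterious predicate
#'
#' A variant is predicted deleterious when its SIFT score is at or below
#' `sift_max` or its PolyPhen-2 score at or above `polyphen_min`. With
#' `stopgain_exempt_from_scores` (default), loss-of-function classes
#' (stop-gain, stop-loss, frameshift, splice) are deleterious regardless of
#' scores. A nonsynonymous variant with both scores absent is not
#' deleterious.
#'
#' @param v Variant table.
#' @param cfg A [filter_config()].
#' @return Logical vector, one per row.
#' @export
is_deleterious <- function(v, cfg = filter_config()) {
  by_score <- (!is.na(v$sift) & v$sift <= cfg$sift_max) |
    (!is.na(v$polyphen) & v$polyphen >= cfg$polyphen_min)
  if (cfg$stopgain_exempt_from_scores) {
    by_score | v$func_class %in% .LOF_CLASSES
  } else {
    by_score
  }
}

#' Fraction of protein lost to a premature stop
#'
#' For a stop codon created at amino-acid position `stop_aa_pos` of a protein
#' of `protein_length` residues, the truncated fraction (the residue at the
#' stop position and everything downstream) as a percentage rounded to one
#' decimal: `100 * (protein_length - stop_aa_pos + 1) / protein_length`.
#'
#' @param stop_aa_pos Amino-acid position of the premature stop (1-based).
#' @param protein_length Length of the reference protein in residues.
#' @return Numeric vector of percentages (1 decimal).
#' @export
truncation_fraction <- function(stop_aa_pos, protein_length) {
  stop_aa_pos <- as.numeric(stop_aa_pos)
  protein_length <- as.numeric(protein_length)
  if (any(stop_aa_pos < 1, na.rm = TRUE)) {
    stop("stop_aa_pos must be >= 1", call. = FALSE)
  }
  if (any(stop_aa_pos > protein_length, na.rm = TRUE)) {
    stop("stop_aa_pos exceeds protein_length", call. = FALSE)
  }
  round(100 * (protein_length - stop_aa_pos + 1) / protein_length, 1)
}
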