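## Candidate-gene screen: tier tallies per gene and the rare/novel shortlist.

#' Default candidate-gene panel for speech and language disorders
#'
#' The 19 genes most robustly implicated in primary speech, language and
#' reading disorders by prior literature, used as the default screen panel.
#'
#' @return Character vector of 19 gene symbols.
#' @export
candidate_genes_default <- function() {
  c("CMIP", "ATP2C2", "CNTNAP2", "NFXL1", "FOXP1", "FOXP2", "DYX1C1",
    "KIAA0319", "DCDC2", "ROBO1", "SRPX2", "GRIN2A", "GRIN2B", "ERC1",
    "SETBP1", "CNTNAP5", "DOCK4", "SEMA6D", "AUTS2")
}

.TIERS <- c("common", "low_frequency", "rare", "novel")

#' Screen variants against a candidate-gene panel
#'
#' Restricts QC-passed variants to the candidate genes (exact,
#' case-insensitive symbol match), tallies them per gene by frequency tier,
#' and returns the rare/novel shortlist with carriers, scores and tier
#' labels, sorted by chromosome and position. Counting is by distinct
#' variant, not (variant, carrier) pair: a variant carried by several
#' probands contributes one call.
#'
#' @param v QC-filtered variant table.
#' @param genes Candidate gene symbols (default [candidate_genes_default()]).
#' @param cfg A [filter_config()].
#' @return List of class `candidate_screen`: `summary` (a
#'   `candidate_summary` data.frame: per-gene tier counts plus an `All` row),
#'   `shortlist` (variant table of tiers novel/rare with a `tier` column),
#'   and `percents` (tier percentage shares of the total, 1 decimal).
#' @export
screen_candidates <- function(v, genes = candidate_genes_default(),
                              cfg = filter_config()) {
  if (!length(genes)) stop("empty candidate gene list", call. = FALSE)
  genes <- unique(genes)
  hit <- toupper(v$gene) %in% toupper(genes)
  cand <- v[hit, , drop = FALSE]
  tier <- if (nrow(cand)) frequency_tier(cand, cfg) else character(0)

  per_gene <- t(vapply(genes, function(g) {
    idx <- toupper(cand$gene) == toupper(g)
    vapply(.TIERS, function(tr) sum(tier[idx] == tr), integer(1))
  }, integer(length(.TIERS))))
  colnames(per_gene) <- .TIERS
  summary <- data.frame(gene = genes, per_gene,
                        total = as.integer(rowSums(per_gene)),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$gene), , drop = FALSE]
  all_row <- data.frame(gene = "All",
                        t(as.integer(colSums(per_gene))),
                        total = as.integer(sum(per_gene)),
                        stringsAsFactors = FALSE)
  names(all_row) <- names(summary)
  summary <- rbind(summary, all_row)
  rownames(summary) <- NULL
  class(summary) <- c("candidate_summary", "data.frame")

  keep <- tier %in% c("novel", "rare")
  shortlist <- cand[keep, , drop = FALSE]
  shortlist$tier <- tier[keep]
  shortlist <- sort_variants(shortlist)
  rownames(shortlist) <- NULL

  totals <- unlist(all_row[.TIERS])
  percents <- if (sum(totals) > 0) tier_percentages(totals) else
    stats::setNames(rep(NA_real_, length(.TIERS)), .TIERS)

  structure(list(summary = summary, shortlist = shortlist,
                 percents = percents),
            class = "candidate_screen")
}

#' @export
print.candidate_screen <- function(x, ...) {
  tot <- x$summary[x$summary$gene == "All", ]
  cat(sprintf("Candidate-gene screen: %d calls (%d novel, %d rare, %d low-frequency, %d common)\n",
              tot$total, tot$novel, tot$rare, tot$low_frequency, tot$common))
  cat(sprintf("Rare/novel shortlist: %d variants in %d genes\n",
              nrow(x$shortlist), length(unique(x$shortlist$gene))))
  invisible(x)
}

#' Tier percentage shares
#'
#' Percentage of total calls in each frequency tier,
#' `100 * count / total` rounded to one decimal.
#'
#' @param counts Named (or ordered) integer vector of per-tier counts.
#' @return Numeric vector of percentages with the same names.
#' @export
tier_percentages <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total count is zero", call. = FALSE)
  round(100 * counts / total, 1)
}
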