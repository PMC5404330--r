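## Pooled hypergeometric over-representation against a background gene list,
## Benjamini-Hochberg adjustment, and frequency-stratified list construction.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe_size, set_size,
#' list_size)`: the probability that a uniform draw of `list_size` genes from
#' a universe containing `set_size` marked genes hits at least `overlap` of
#' them. Accumulated in log space (`lchoose` + log-sum-exp) for numerical
#' stability in deep tails.
#'
#' @param overlap Observed overlap count.
#' @param set_size Number of marked genes (gene-set size within the universe).
#' @param list_size Size of the drawn list.
#' @param universe_size Universe size.
#' @return Probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(overlap, set_size, list_size, universe_size) {
  k <- as.numeric(overlap); K <- as.numeric(set_size)
  n <- as.numeric(list_size); N <- as.numeric(universe_size)
  if (k < 0 || K < 0 || n < 0 || N < 0 ||
      K > N || n > N || k > min(K, n)) {
    stop("hypergeometric bounds violated: need overlap <= min(set, list) and set, list <= universe",
         call. = FALSE)
  }
  if (k == 0) return(1)
  i <- seq(k, min(K, n))
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m + log(sum(exp(log_terms - m))))
  min(p, 1)
}

#' Gene-set over-representation of a gene list
#'
#' Tests each gene set for enrichment of `gene_list` against `background`
#' with a one-sided hypergeometric test, reporting the expected overlap
#' (`exp_count = set_size * list_size / universe_size`), observed overlap,
#' upper-tail p-value and Benjamini-Hochberg FDR computed over all tested
#' sets. Set membership is restricted to background genes; sets smaller than
#' `min_set_size` (within the background) are not tested.
#'
#' @param gene_list Character vector (must be a subset of `background`).
#' @param background Character vector: the gene universe.
#' @param sets A `gene_set_collection`.
#' @param p_threshold,fdr_threshold Report thresholds (default 0.01 each).
#' @param min_set_size Only sets with more than this many background genes
#'   are reported (default 10, matching the "size > 10 genes" table rule).
#' @param filter Return only rows passing the thresholds (default TRUE);
#'   with `FALSE` the full tested table is returned with a `significant`
#'   column.
#' @return data.frame of class `enrichment_result`: `set_id`, `term`,
#'   `set_size`, `exp_count`, `count`, `p`, `fdr`, sorted by `p`.
#' @export
enrich <- function(gene_list, background, sets,
                   p_threshold = 0.01, fdr_threshold = 0.01,
                   min_set_size = 10L, filter = TRUE) {
  background <- unique(background)
  if (!length(background)) stop("empty background gene list", call. = FALSE)
  gene_list <- unique(gene_list)
  if (length(setdiff(gene_list, background))) {
    stop("gene_list contains genes outside the background", call. = FALSE)
  }
  N <- length(background); n <- length(gene_list)
  members <- lapply(sets$sets, intersect, background)
  tested <- names(members)[lengths(members) > 0]
  rows <- lapply(tested, function(id) {
    K <- length(members[[id]])
    k <- length(intersect(members[[id]], gene_list))
    data.frame(
      set_id = id, term = unname(sets$names[id]), set_size = K,
      exp_count = K * n / N, count = k,
      p = hypergeom_upper_tail(k, K, n, N),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    set_id = character(0), term = character(0), set_size = integer(0),
    exp_count = numeric(0), count = integer(0), p = numeric(0),
    stringsAsFactors = FALSE
  )
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  out$significant <- out$p < p_threshold & out$fdr < fdr_threshold &
    out$set_size > min_set_size
  if (filter) {
    out <- out[out$significant, , drop = FALSE]
    out$significant <- NULL
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Gene-set enrichment: %d rows\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 15), digits = 4)
  invisible(x)
}

#' Frequency-stratified gene lists
#'
#' Applies the relaxed exome-wide filter -- nonsynonymous, stop-gain and
#' stop-loss variants with 1000 Genomes frequency at or below 5% (or absent),
#' regardless of SIFT/PolyPhen predictions -- and assigns each variant's gene
#' to exactly one stratum by the variant's frequency: `novel` (absent from
#' both panels), `rare_reported` (reported in 1000 Genomes below 1%), or
#' `low_frequency` (1000 Genomes frequency between 1% and 5% inclusive).
#' Variants absent from 1000 Genomes but present in the other panel fit no
#' stratum and are dropped. Genes may appear in several strata via different
#' variants.
#'
#' @param v QC-filtered variant table.
#' @param cfg A [filter_config()] (supplies the 1% and 5% cuts).
#' @return Named list of three character vectors: `novel`, `rare_reported`,
#'   `low_frequency`.
#' @export
stratify_by_frequency <- function(v, cfg = filter_config()) {
  relaxed <- v$func_class %in% c("nonsynonymous_snv", "stopgain", "stoploss") &
    (is.na(v$freq_kg) | v$freq_kg <= cfg$low_freq_threshold)
  v <- v[relaxed, , drop = FALSE]
  novel <- is.na(v$freq_kg) & is.na(v$freq_evs)
  rare_rep <- !is.na(v$freq_kg) & v$freq_kg < cfg$rare_threshold
  low <- !is.na(v$freq_kg) & v$freq_kg >= cfg$rare_threshold &
    v$freq_kg <= cfg$low_freq_threshold
  list(
    novel = sort(unique(v$gene[novel])),
    rare_reported = sort(unique(v$gene[rare_rep])),
    low_frequency = sort(unique(v$gene[low]))
  )
}
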