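## Within-proband pathway mapping, the shared-pathway count statistic and the
## permutation-based empirical FDR.
##
## The "FDR" here is the per-pathway empirical permutation tail probability
## (the number of permutations in which a pathway is shared by at least as
## many probands as observed, divided by the number of permutations), as used
## in the source analysis; no cross-pathway correction is applied by default.

#' Per-proband qualifying gene sets
#'
#' For each carrier proband, the deduplicated genes of that proband's
#' qualifying variants: protein-disruptive class (nonsynonymous,
#' stop-gain/loss, splice, frameshift), tier novel or rare, predicted
#' deleterious, outside segmental duplications. Probands with no qualifying
#' variants keep an empty gene list (they still count toward the cohort
#' size).
#'
#' @param v QC-filtered variant table.
#' @param cfg A [filter_config()].
#' @param probands Optional character vector fixing the cohort (probands with
#'   no qualifying variants included); defaults to all carriers seen in `v`.
#' @return Named list of character vectors, one per proband.
#' @export
proband_gene_sets <- function(v, cfg = filter_config(), probands = NULL) {
  long_all <- expand_carriers(v)
  if (is.null(probands)) probands <- sort(unique(long_all$proband))
  qual <- v[.qualifies_disruptive(v, cfg), , drop = FALSE]
  long <- expand_carriers(qual)
  out <- lapply(probands, function(p) sort(unique(long$gene[long$proband == p])))
  stats::setNames(out, probands)
}

#' Number of probands sharing a pathway
#'
#' @param gene_sets Named list of per-proband gene lists.
#' @param pathway Character vector of pathway member genes.
#' @return Integer: probands whose gene list intersects the pathway.
#' @export
shared_count <- function(gene_sets, pathway) {
  sum(vapply(gene_sets, function(g) any(g %in% pathway), logical(1)))
}

#' Permutation test for pathway sharing across probands
#'
#' For each permutation, every proband is assigned a uniform random sample
#' (without replacement) from the gene universe of the same size as its
#' observed gene list, and the shared-proband count is recomputed per
#' pathway. The empirical FDR of a pathway is the fraction of permutations
#' in which it is shared by at least as many probands as observed
#' (`perm_geq / n_perm`; ties count, so the estimator's floor is 0 and its
#' grid is `1/n_perm`).
#'
#' @param gene_sets Named list of per-proband observed gene lists.
#' @param pathways A `gene_set_collection`.
#' @param universe Character vector: all genes with variants (every observed
#'   gene list must be a subset).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; recorded in the output.
#' @param cohort_over_half Threshold column flag: pathways shared by more
#'   than half of the cohort are marked.
#' @return data.frame of class `pathway_share`: `set_id`, `set_name`,
#'   `observed_probands`, `perm_geq`, `fdr`, `over_half`, `n_perm`, `seed`,
#'   sorted by (fdr, -observed, set_id).
#' @export
permutation_fdr <- function(gene_sets, pathways, universe, n_perm = 1000L,
                            seed = 1L, cohort_over_half = TRUE) {
  stopifnot(n_perm >= 1)
  universe <- unique(universe)
  sizes <- lengths(gene_sets)
  if (any(sizes > length(universe))) {
    stop("a proband gene list is larger than the universe", call. = FALSE)
  }
  extra <- setdiff(unique(unlist(gene_sets)), universe)
  if (length(extra)) {
    stop("proband gene lists contain genes outside the universe: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  set_ids <- names(pathways$sets)
  ## membership matrix: universe genes x pathways
  member <- vapply(pathways$sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, set_ids))

  count_shared <- function(lists_idx) {
    ## lists_idx: list of integer indices into universe, one per proband
    hits <- matrix(0L, nrow = length(lists_idx), ncol = length(set_ids))
    for (i in seq_along(lists_idx)) {
      idx <- lists_idx[[i]]
      if (length(idx)) {
        hits[i, ] <- as.integer(colSums(member[idx, , drop = FALSE]) > 0L)
      }
    }
    colSums(hits)
  }

  obs_idx <- lapply(gene_sets, function(g) match(g, universe))
  observed <- count_shared(obs_idx)

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = .GlobalEnv))
  set.seed(seed)
  perm_geq <- integer(length(set_ids))
  nU <- length(universe)
  for (b in seq_len(n_perm)) {
    perm_idx <- lapply(sizes, function(k) if (k) sample.int(nU, k) else integer(0))
    perm_geq <- perm_geq + as.integer(count_shared(perm_idx) >= observed)
  }

  out <- data.frame(
    set_id = set_ids,
    set_name = unname(pathways$names[set_ids]),
    observed_probands = as.integer(observed),
    perm_geq = perm_geq,
    fdr = perm_geq / n_perm,
    over_half = observed > length(gene_sets) / 2,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr, -out$observed_probands, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_share", "data.frame")
  out
}

#' @export
print.pathway_share <- function(x, ...) {
  cat(sprintf("Pathway sharing: %d pathways, %d probands, %d permutations (seed %d)\n",
              nrow(x), attr(x, "cohort_size") %||% NA_integer_,
              x$n_perm[1], x$seed[1]))
  sig <- x[x$fdr < 0.01 & x$over_half, , drop = FALSE]
  cat(sprintf("  %d pathways with empirical FDR < 0.01 shared by > half of probands\n",
              nrow(sig)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
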