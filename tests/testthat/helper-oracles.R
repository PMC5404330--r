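# Independent oracles and small generators used across the suite.
# The oracles re-state the screening rules literally, without calling the
# package's classification helpers, so they stay independent of the code
# paths they check.

# Literal brute-force compound-het enumeration: for every (proband, gene)
# pair, apply the qualifying predicates directly, remove both members of any
# pair within the proximity window, and keep groups of >= 2.
oracle_comphet <- function(v, proximity_bp = 10, rare_cut = 0.01,
                           sift_max = 0.05, polyphen_min = 0.85) {
  lof <- c("stopgain", "stoploss", "frameshift_ins", "frameshift_del", "splice")
  disruptive <- c("nonsynonymous_snv", lof)
  out <- list()
  probands <- unique(unlist(strsplit(v$carriers[!is.na(v$carriers)], ",")))
  for (p in sort(trimws(probands))) {
    carried <- vapply(seq_len(nrow(v)), function(i) {
      !is.na(v$carriers[i]) &&
        p %in% trimws(strsplit(v$carriers[i], ",")[[1]])
    }, logical(1))
    for (g in sort(unique(v$gene[carried]))) {
      rows <- v[carried & v$gene == g, , drop = FALSE]
      rows <- rows[!duplicated(paste(rows$chrom, rows$pos, rows$ref, rows$alt)), ,
                   drop = FALSE]
      keep <- logical(nrow(rows))
      for (i in seq_len(nrow(rows))) {
        cls_ok <- rows$func_class[i] %in% disruptive
        f_kg <- rows$freq_kg[i]; f_evs <- rows$freq_evs[i]
        tier_ok <- if (is.na(f_kg) && is.na(f_evs)) TRUE else
          max(f_kg, f_evs, na.rm = TRUE) < rare_cut
        del_ok <- (!is.na(rows$sift[i]) && rows$sift[i] <= sift_max) ||
          (!is.na(rows$polyphen[i]) && rows$polyphen[i] >= polyphen_min) ||
          rows$func_class[i] %in% lof
        seg_ok <- !isTRUE(rows$segdup[i])
        keep[i] <- cls_ok && tier_ok && del_ok && seg_ok
      }
      rows <- rows[keep, , drop = FALSE]
      if (nrow(rows) < 2) next
      close <- logical(nrow(rows))
      for (i in seq_len(nrow(rows) - 1)) {
        for (j in seq(i + 1, nrow(rows))) {
          if (rows$chrom[i] == rows$chrom[j] &&
              abs(rows$pos[i] - rows$pos[j]) <= proximity_bp) {
            close[i] <- close[j] <- TRUE
          }
        }
      }
      rows <- rows[!close, , drop = FALSE]
      if (nrow(rows) < 2) next
      out[[length(out) + 1L]] <- list(
        proband = p, gene = g,
        keys = sort(paste(rows$chrom, rows$pos, rows$ref, rows$alt, sep = ":"))
      )
    }
  }
  out
}

# Canonical form of a comphet_set for comparison with the oracle.
comphet_canonical <- function(cc) {
  out <- lapply(cc, function(g) {
    list(proband = g$proband, gene = g$gene,
         keys = sort(variant_key(g$variants)))
  })
  out[order(vapply(out, function(x) paste(x$proband, x$gene), ""))]
}

# Random small cohort exercising every predicate branch: mixed classes,
# tiers (including NA panels), scores, segdup flags, near-position pairs and
# multi-carrier cells.
random_cohort <- function(n_variants = 150, n_probands = 15, n_genes = 25) {
  probands <- sprintf("P%02d", seq_len(n_probands))
  genes <- sprintf("G%02d", seq_len(n_genes))
  gene_of <- sample(genes, n_variants, replace = TRUE)
  chrom_of_gene <- stats::setNames(
    paste0("chr", sample(1:22, n_genes, replace = TRUE)), genes)
  # cluster positions per gene so proximity exclusion fires sometimes
  pos <- 100000L * match(gene_of, genes) +
    sample(c(1:30, seq(100, 5000, by = 7)), n_variants, replace = TRUE)
  f1 <- ifelse(runif(n_variants) < 0.3, NA_real_,
               signif(runif(n_variants, 0, 0.05), 3))
  f2 <- ifelse(runif(n_variants) < 0.3, NA_real_,
               signif(runif(n_variants, 0, 0.05), 3))
  carr <- vapply(seq_len(n_variants), function(i) {
    k <- sample(0:3, 1, prob = c(0.1, 0.6, 0.2, 0.1))
    if (!k) NA_character_ else paste(sample(probands, k), collapse = ",")
  }, character(1))
  ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  variant_table(
    chrom = unname(chrom_of_gene[gene_of]), pos = pos, ref = ref, alt = alt,
    gene = gene_of,
    func_class = sample(func_classes(), n_variants, replace = TRUE,
                        prob = c(8, 2, 1, 2, 1, 1, 1, 2, 1, 1, 1, 1)),
    carriers = carr,
    freq_kg = f1, freq_evs = f2,
    sift = ifelse(runif(n_variants) < 0.2, NA_real_,
                  round(runif(n_variants), 2)),
    polyphen = ifelse(runif(n_variants) < 0.2, NA_real_,
                      round(runif(n_variants), 2)),
    segdup = runif(n_variants) < 0.1,
    min_depth = sample(5:60, n_variants, replace = TRUE)
  )
}

# Exhaustive hypergeometric upper tail: enumerate every size-n subset of a
# universe with the first K elements marked and count overlaps directly.
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Compact nuclear-family builder for segregation tests: genotypes given as a
# named list variant key -> named gt vector by individual id.
mk_family <- function(fid = "F1", n_sibs = 2,
                      els = NULL, rls = NULL, gts = list()) {
  kids <- c(paste0(fid, "_P"),
            if (n_sibs > 0) paste0(fid, "_S", seq_len(n_sibs)))
  iids <- c(paste0(fid, "_D"), paste0(fid, "_M"), kids)
  n <- length(iids)
  if (is.null(els)) els <- c(NA, NA, rep(100, length(kids)))
  if (is.null(rls)) rls <- c(NA, NA, rep(100, length(kids)))
  ped <- data.frame(
    fid = fid, iid = iids,
    father = c(NA, NA, rep(paste0(fid, "_D"), length(kids))),
    mother = c(NA, NA, rep(paste0(fid, "_M"), length(kids))),
    sex = c("male", "female", rep("unknown", length(kids))),
    role = c("parent", "parent", "proband",
             rep("sibling", length(kids) - 1)),
    els = els, rls = rls, nwr = NA_real_, viq = NA_real_, piq = NA_real_,
    stringsAsFactors = FALSE
  )
  ped$affected <- "unknown"
  is_kid <- ped$role != "parent"
  ped$affected[is_kid] <- affection_status(ped$els[is_kid], ped$rls[is_kid])
  class(ped) <- c("sli_ped", "data.frame")
  geno <- do.call(rbind, lapply(names(gts), function(key) {
    data.frame(key = key, iid = names(gts[[key]]), gt = unname(gts[[key]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(geno)) {
    geno <- data.frame(key = character(0), iid = character(0),
                       gt = character(0), stringsAsFactors = FALSE)
  }
  list(ped = ped, genotypes = geno)
}
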