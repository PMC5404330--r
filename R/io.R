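## Readers/writers for the annotated-variant TSV dialect, PED pedigrees,
## GMT gene sets, plain gene lists and a minimal VCF subset.
##
## Dialect: 17 tab-separated columns, header required, "NA" is the sole
## missing-value token (an empty cell is an error -- guards silent column
## drift). Frequency columns are percentages on disk (the source tables print
## "0.08%"), fractions in memory.

#' Read an annotated-variant table
#'
#' Parses the 17-column tab-separated dialect. Columns named with suffix
#' `_pct` are percentages on disk and are divided by 100 into fractions.
#' `"NA"` is the only missing-value token; an empty cell is an error.
#'
#' @param path Path to a TSV file with the dialect header.
#' @return A `sli_variants` data.frame (see [variant_table()]); carrier
#'   proband identifiers remain comma-separated in the `carriers` column and
#'   can be expanded with [expand_carriers()].
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file (header required)", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .DIALECT_COLUMNS)) {
    stop(path, ": header does not match the variant-table dialect", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  n <- length(body)

  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  chr <- identity
  na_of <- list(numeric = NA_real_, integer = NA_integer_,
                character = NA_character_, `0/1 flag` = NA_integer_)
  get <- function(parsed, line_no, col, what, parse) {
    raw <- parsed[[match(col, .DIALECT_COLUMNS)]]
    if (!nzchar(raw)) {
      stop(sprintf("%s, line %d: empty cell in column '%s' (use NA)",
                   path, line_no, col), call. = FALSE)
    }
    if (raw == "NA") return(na_of[[what]])
    out <- parse(raw)
    if (is.na(out)) {
      stop(sprintf("%s, line %d: cannot parse %s value '%s' in column '%s'",
                   path, line_no, what, raw, col), call. = FALSE)
    }
    out
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- cells[[i]]
    line_no <- i + 1L
    if (length(p) != length(.DIALECT_COLUMNS)) {
      stop(sprintf("%s, line %d: expected %d tab-separated fields, found %d",
                   path, line_no, length(.DIALECT_COLUMNS), length(p)),
           call. = FALSE)
    }
    kg_pct <- get(p, line_no, "freq_kg_pct", "numeric", num)
    evs_pct <- get(p, line_no, "freq_evs_pct", "numeric", num)
    for (val in c(kg = kg_pct, evs = evs_pct)) {
      if (!is.na(val) && (val < 0 || val > 100)) {
        stop(sprintf("%s, line %d: percent frequency %g outside [0, 100]",
                     path, line_no, val), call. = FALSE)
      }
    }
    segdup_raw <- get(p, line_no, "segdup", "0/1 flag", int)
    if (!is.na(segdup_raw) && !segdup_raw %in% c(0L, 1L)) {
      stop(sprintf("%s, line %d: segdup must be 0 or 1", path, line_no),
           call. = FALSE)
    }
    rows[[i]] <- data.frame(
      chrom = get(p, line_no, "chrom", "character", chr),
      pos = get(p, line_no, "pos", "integer", int),
      rsid = if (p[3] == ".") NA_character_ else get(p, line_no, "rsid", "character", chr),
      ref = get(p, line_no, "ref", "character", chr),
      alt = get(p, line_no, "alt", "character", chr),
      carriers = get(p, line_no, "carriers", "character", chr),
      freq_kg = if (is.na(kg_pct)) NA_real_ else kg_pct / 100,
      freq_evs = if (is.na(evs_pct)) NA_real_ else evs_pct / 100,
      gene = get(p, line_no, "gene", "character", chr),
      func_class = get(p, line_no, "func_class", "character", chr),
      coding_change = get(p, line_no, "coding_change", "character", chr),
      phylop = get(p, line_no, "phylop", "numeric", num),
      phastcons = get(p, line_no, "phastcons", "numeric", num),
      sift = get(p, line_no, "sift", "numeric", num),
      polyphen = get(p, line_no, "polyphen", "numeric", num),
      segdup = as.logical(segdup_raw),
      min_depth = get(p, line_no, "min_depth", "integer", int),
      stringsAsFactors = FALSE
    )
  }
  v <- if (n) do.call(rbind, rows) else utils::read.delim(
    text = paste(c(.DIALECT_COLUMNS, ""), collapse = "\t"), sep = "\t"
  )[0, ]
  if (!n) {
    v <- variant_table(character(0), integer(0), character(0), character(0),
                       character(0), character(0))
    return(v)
  }
  validate_variants(v, where = path)
  class(v) <- c("sli_variants", "data.frame")
  v
}

## Format a fraction as a percent string that parses back to the same double
## (exact for values with <= 4 decimal digits of percent).
.fmt_pct <- function(x) {
  ifelse(is.na(x), "NA", formatC(x * 100, format = "fg", digits = 15, width = 1))
}
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "fg", digits = 15, width = 1))
}
.fmt_chr <- function(x) ifelse(is.na(x), "NA", as.character(x))

#' Write an annotated-variant table in the TSV dialect
#'
#' Inverse of [read_variant_table()]: fractions are written as percent
#' columns, `NA` as the literal token `NA`, rsid `NA` as `.`. Rows are
#' written in the order given; use [write_report_tables()] for the sorted
#' report bundle.
#'
#' @param v Variant table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(v, path) {
  fields <- list(.fmt_chr(v$chrom), .fmt_num(v$pos),
                 ifelse(is.na(v$rsid), ".", v$rsid),
                 .fmt_chr(v$ref), .fmt_chr(v$alt), .fmt_chr(v$carriers),
                 .fmt_pct(v$freq_kg), .fmt_pct(v$freq_evs),
                 .fmt_chr(v$gene), .fmt_chr(v$func_class),
                 .fmt_chr(v$coding_change),
                 .fmt_num(v$phylop), .fmt_num(v$phastcons),
                 .fmt_num(v$sift), .fmt_num(v$polyphen),
                 ifelse(v$segdup, "1", "0"), .fmt_num(v$min_depth))
  lines <- do.call(paste, c(fields, sep = "\t"))
  header <- paste(.DIALECT_COLUMNS, collapse = "\t")
  writeLines(c(header, if (nrow(v)) lines), path)
  invisible(path)
}

#' Read an extended PED pedigree file
#'
#' Standard 6-column PED (family, individual, father, mother, sex, phenotype)
#' extended with five quantitative phenotype columns: `els`, `rls` (CELF-R
#' expressive/receptive language scores), `nwr` (nonword repetition), `viq`
#' and `piq` (verbal / performance IQ), all standardized to mean 100, SD 15,
#' `NA` when missing. Affection status is derived from `els`/`rls` via
#' [affection_status()] (children only; the language tests are child-normed,
#' so parents are always `unknown`).
#'
#' Within each family, individuals with at least one named parent are
#' children; the first-listed child is taken as the proband.
#'
#' @param path Path to the PED file (whitespace-separated).
#' @return A `sli_ped` data.frame with one row per individual: `fid`, `iid`,
#'   `father`, `mother`, `sex` (`male`/`female`/`unknown`), `role`
#'   (`proband`/`sibling`/`parent`), the five scores, and `affected`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           na.strings = "NA", comment.char = "#")
  if (ncol(raw) != 11L) {
    stop(path, ": expected 11 columns (6 PED + els rls nwr viq piq), found ",
         ncol(raw), call. = FALSE)
  }
  names(raw) <- c("fid", "iid", "father", "mother", "sex", "pheno",
                  "els", "rls", "nwr", "viq", "piq")
  for (col in c("fid", "iid", "father", "mother")) {
    raw[[col]] <- as.character(raw[[col]])
  }
  raw$father[raw$father %in% c("0", NA)] <- NA_character_
  raw$mother[raw$mother %in% c("0", NA)] <- NA_character_
  raw$sex <- c("male", "female")[match(raw$sex, c(1, 2))]
  raw$sex[is.na(raw$sex)] <- "unknown"

  ## structural checks, per family
  for (fid in unique(raw$fid)) {
    fam <- raw[raw$fid == fid, ]
    if (anyDuplicated(fam$iid)) {
      stop(sprintf("%s: duplicate individual id '%s' in family %s",
                   path, fam$iid[duplicated(fam$iid)][1], fid), call. = FALSE)
    }
    for (i in seq_len(nrow(fam))) {
      for (par in c("father", "mother")) {
        p <- fam[[par]][i]
        if (is.na(p)) next
        if (p == fam$iid[i]) {
          stop(sprintf("%s: individual '%s' in family %s is its own parent",
                       path, p, fid), call. = FALSE)
        }
        if (!p %in% fam$iid) {
          stop(sprintf("%s: individual '%s' in family %s references unknown %s '%s'",
                       path, fam$iid[i], fid, par, p), call. = FALSE)
        }
      }
    }
  }
  bad <- vapply(c("els", "rls", "nwr", "viq", "piq"),
                function(col) any(!is.na(raw[[col]]) & raw[[col]] < 0), TRUE)
  if (any(bad)) stop(path, ": negative phenotype score", call. = FALSE)

  is_child <- !is.na(raw$father) | !is.na(raw$mother)
  raw$role <- ifelse(is_child, "sibling", "parent")
  for (fid in unique(raw$fid)) {
    idx <- which(raw$fid == fid & is_child)
    if (length(idx)) raw$role[idx[1]] <- "proband"
  }
  raw$affected <- "unknown"
  raw$affected[is_child] <- affection_status(raw$els[is_child], raw$rls[is_child])
  raw$pheno <- NULL
  class(raw) <- c("sli_ped", "data.frame")
  raw
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id <TAB> description <TAB> gene...`.
#' Duplicate genes within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors keyed by set id) and `names` (named character vector of set
#'   descriptions).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); nms <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("%s, line %d: GMT lines need >= 3 tab-separated fields",
                   path, i), call. = FALSE)
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      stop(sprintf("%s, line %d: empty gene-set member list", path, i),
           call. = FALSE)
    }
    sets[[f[1]]] <- genes
    nms[f[1]] <- f[2]
  }
  gene_set_collection(sets, nms)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (members, deduplicated here).
#' @param names Optional named character vector of set descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  sets <- lapply(sets, unique)
  if (any(!lengths(sets))) stop("gene sets must be non-empty", call. = FALSE)
  if (is.null(names)) {
    names <- stats::setNames(base::names(sets), base::names(sets))
  }
  structure(list(sets = sets, names = names), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, unname(gsc$names[id]), gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path Path to the file; blank lines and `#` comments are ignored.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Import a minimal VCF as an annotated-variant table
#'
#' Consumes a VCF v4.2 subset with the INFO keys `GENE`, `FC` (functional
#' class), `KG_AF`, `EVS_AF`, `SIFT`, `PP2`, `PHYLOP`, `PHASTCONS`, `SEGDUP`,
#' `DP_MIN` and per-sample `GT`. Missing INFO keys become absent fields;
#' multi-allelic sites are split into one record per alternate allele (with
#' per-allele INFO values split on commas where present).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return List with `variants` (a `sli_variants` table whose `carriers`
#'   column holds the samples carrying each alternate allele) and `genotypes`
#'   (long data.frame: `key`, `iid`, `gt` with levels `hom_ref`, `het`,
#'   `hom_alt`, `missing`).
#' @export
import_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || !ncol(gt_raw) || !"FORMAT" %in% colnames(gt_raw)) {
    stop(path, ": VCF has no genotype (FORMAT/GT) section", call. = FALSE)
  }
  samples <- setdiff(colnames(gt_raw), "FORMAT")
  if (nrow(fix) == 0) {
    return(list(
      variants = variant_table(character(0), integer(0), character(0),
                               character(0), character(0), character(0)),
      genotypes = data.frame(key = character(0), iid = character(0),
                             gt = character(0), stringsAsFactors = FALSE)
    ))
  }

  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  parse_allele_val <- function(raw, a, n_alt, as_num = TRUE) {
    if (is.na(raw)) return(if (as_num) NA_real_ else NA_character_)
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    val <- if (length(parts) >= n_alt) parts[a] else parts[1]
    if (val %in% c(".", "NA", "")) return(if (as_num) NA_real_ else NA_character_)
    if (as_num) suppressWarnings(as.numeric(val)) else val
  }

  rows <- list(); geno <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i]
    fmt <- strsplit(gt_raw[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) {
      stop(sprintf("%s: record %s:%s has no GT in FORMAT", path,
                   fix$CHROM[i], fix$POS[i]), call. = FALSE)
    }
    gts <- vapply(samples, function(s) {
      strsplit(gt_raw[i, s], ":", fixed = TRUE)[[1]][gt_idx]
    }, character(1))
    alleles <- strsplit(gsub("\\|", "/", gts), "/", fixed = FALSE)

    for (a in seq_along(alts)) {
      key <- variant_key(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[a])
      n_alt_allele <- vapply(alleles, function(al) {
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      gt_call <- ifelse(is.na(n_alt_allele), "missing",
                        c("hom_ref", "het", "hom_alt")[n_alt_allele + 1L])
      carriers <- samples[gt_call %in% c("het", "hom_alt")]
      geno[[length(geno) + 1L]] <- data.frame(
        key = key, iid = samples, gt = unname(gt_call),
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- variant_table(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i],
        carriers = if (length(carriers)) paste(carriers, collapse = ",") else NA_character_,
        gene = parse_allele_val(info_field(info, "GENE"), a, length(alts), FALSE),
        func_class = parse_allele_val(info_field(info, "FC"), a, length(alts), FALSE),
        coding_change = parse_allele_val(info_field(info, "CC"), a, length(alts), FALSE),
        freq_kg = parse_allele_val(info_field(info, "KG_AF"), a, length(alts)),
        freq_evs = parse_allele_val(info_field(info, "EVS_AF"), a, length(alts)),
        sift = parse_allele_val(info_field(info, "SIFT"), a, length(alts)),
        polyphen = parse_allele_val(info_field(info, "PP2"), a, length(alts)),
        phylop = parse_allele_val(info_field(info, "PHYLOP"), a, length(alts)),
        phastcons = parse_allele_val(info_field(info, "PHASTCONS"), a, length(alts)),
        segdup = !is.na(info_field(info, "SEGDUP")) &&
          info_field(info, "SEGDUP") %in% c("1", "TRUE"),
        min_depth = {
          d <- parse_allele_val(info_field(info, "DP_MIN"), a, length(alts))
          if (is.na(d)) 30L else as.integer(d)
        }
      )
    }
  }
  variants <- do.call(rbind, rows)
  class(variants) <- c("sli_variants", "data.frame")
  list(variants = variants, genotypes = do.call(rbind, geno))
}

#' Write the screen report bundle
#'
#' Emits the screen outputs as TSV files under `dir` with deterministic
#' column order and rows sorted by chromosome then position. Variant-shaped
#' tables are written in the 17-column dialect (so they round-trip through
#' [read_variant_table()]); summary and annotation tables are plain TSVs.
#'
#' @param results Named list; recognised elements: `candidate_summary`,
#'   `candidate_shortlist`, `stopgains`, `comphet`, `multihit`,
#'   `segregation`, `pathway_share`, `enrichment` (missing ones are skipped).
#' @param dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("cannot write to directory: ", dir, call. = FALSE)
  }
  written <- character(0)
  emit_variants <- function(v, name) {
    v <- sort_variants(v)
    p <- file.path(dir, name)
    write_variant_table(v[, .DIALECT_COLUMNS_INTERNAL, drop = FALSE], p)
    written <<- c(written, p)
  }
  emit_plain <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    written <<- c(written, p)
  }
  r <- results
  if (!is.null(r$candidate_shortlist)) {
    emit_variants(r$candidate_shortlist, "candidate_shortlist.tsv")
  }
  if (!is.null(r$stopgains)) emit_variants(r$stopgains, "stopgain_screen.tsv")
  if (!is.null(r$candidate_summary)) {
    emit_plain(r$candidate_summary, "candidate_summary.tsv")
  }
  if (!is.null(r$comphet)) emit_plain(comphet_as_table(r$comphet), "comphet_candidates.tsv")
  if (!is.null(r$multihit)) emit_plain(r$multihit, "multihit_probands.tsv")
  if (!is.null(r$segregation)) emit_plain(r$segregation, "segregation.tsv")
  if (!is.null(r$pathway_share)) emit_plain(r$pathway_share, "pathway_share.tsv")
  if (!is.null(r$enrichment)) emit_plain(r$enrichment, "go_enrichment.tsv")
  invisible(written)
}

## Internal column set of variant tables (fraction-scale columns).
.DIALECT_COLUMNS_INTERNAL <- c(
  "chrom", "pos", "rsid", "ref", "alt", "carriers",
  "freq_kg", "freq_evs", "gene", "func_class", "coding_change",
  "phylop", "phastcons", "sift", "polyphen", "segdup", "min_depth"
)

#' Sort a variant table by chromosome then position
#'
#' Chromosomes sort numerically where possible (`chr2` before `chr11`), with
#' X, Y and MT after the autosomes.
#'
#' @param v Variant table.
#' @return The sorted table.
#' @export
sort_variants <- function(v) {
  chrom_rank <- function(ch) {
    x <- sub("^chr", "", ch)
    num <- suppressWarnings(as.integer(x))
    num[x == "X"] <- 23L; num[x == "Y"] <- 24L
    num[x %in% c("M", "MT")] <- 25L
    ifelse(is.na(num), 26L, num)
  }
  v[order(chrom_rank(v$chrom), v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
}
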