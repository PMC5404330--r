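#' sliexome: exome variant prioritization for SLI family studies
#'
#' Tools for post-annotation prioritization of exome variants in nuclear
#' families ascertained for specific language impairment: frequency tiering,
#' candidate-gene / stop-gain / compound-heterozygote / multiple-hit screens,
#' within-family segregation analysis, a permutation-based pathway-sharing
#' test, hypergeometric gene-set enrichment, and a seeded synthetic-cohort
#' generator for end-to-end recovery testing.
#'
#' Coordinates are 1-based inclusive throughout ("chr12:1137072" style, as in
#' VCF). Allele frequencies are stored internally as fractions in `[0, 1]`;
#' the on-disk table dialect carries percent columns (`*_pct`).
#'
#' @name sliexome-package
#' @keywords internal
#' @importFrom stats p.adjust phyper rbeta rbinom rnorm rpois runif setNames
#' @importFrom utils head read.delim read.table write.table
"_PACKAGE"

## Functional-class enumeration of the annotated-variant model.
.FUNC_CLASSES <- c(
  "nonsynonymous_snv", "stopgain", "stoploss", "splice",
  "frameshift_ins", "frameshift_del", "nonframeshift_indel",
  "synonymous", "intronic", "intergenic", "ncRNA", "UTR"
)

## Classes retained by the post-annotation exclusion filter (protein-affecting).
.CODING_CLASSES <- c(
  "nonsynonymous_snv", "stopgain", "stoploss", "splice",
  "frameshift_ins", "frameshift_del", "nonframeshift_indel"
)

## Classes eligible for the compound-het / pathway "disruptive" predicate
## (nonframeshift indels are not counted as disruptive).
.DISRUPTIVE_CLASSES <- c(
  "nonsynonymous_snv", "stopgain", "stoploss", "splice",
  "frameshift_ins", "frameshift_del"
)

## Loss-of-function classes exempt from the SIFT/PolyPhen predicate by default.
.LOF_CLASSES <- c("stopgain", "stoploss", "frameshift_ins", "frameshift_del", "splice")

## Column order of the annotated-variant TSV dialect (17 columns).
.DIALECT_COLUMNS <- c(
  "chrom", "pos", "rsid", "ref", "alt", "carriers",
  "freq_kg_pct", "freq_evs_pct", "gene", "func_class", "coding_change",
  "phylop", "phastcons", "sift", "polyphen", "segdup", "min_depth"
)

#' Functional class levels of the annotated-variant model
#'
#' @return Character vector of the twelve recognised functional classes.
#' @export
func_classes <- function() .FUNC_CLASSES

#' Build a compact key identifying a variant
#'
#' Keys have the form `chrom:pos:ref:alt` and identify one alternate allele
#' at one position.
#'
#' @param chrom,pos,ref,alt Vectors of the four identifying fields, or a
#'   variant table as returned by [read_variant_table()] passed as `chrom`
#'   with the rest missing.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    v <- chrom
    return(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct an annotated-variant table in memory
#'
#' Convenience constructor used by the simulator, fixtures and tests. All
#' frequency/score arguments are fractions or scores on their native scales;
#' `NA` marks an absent annotation.
#'
#' @param chrom,pos,ref,alt Identifying fields (`pos` 1-based).
#' @param gene Gene symbol.
#' @param func_class One of [func_classes()].
#' @param carriers Comma-separated proband identifiers carrying the variant.
#' @param rsid dbSNP identifier or `NA`.
#' @param freq_kg,freq_evs Panel allele frequencies as fractions in `[0,1]`.
#' @param sift,polyphen,phylop,phastcons Prediction/conservation scores.
#' @param coding_change Free-text transcript annotation.
#' @param segdup Logical; inside a known segmental duplication.
#' @param min_depth Minimum read depth across carriers.
#' @return A `data.frame` of class `sli_variants`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gene, func_class,
                          carriers = NA_character_, rsid = NA_character_,
                          freq_kg = NA_real_, freq_evs = NA_real_,
                          sift = NA_real_, polyphen = NA_real_,
                          phylop = NA_real_, phastcons = NA_real_,
                          coding_change = NA_character_,
                          segdup = FALSE, min_depth = 30L) {
  n <- max(lengths(list(chrom, pos, ref, alt, gene, func_class, carriers,
                        rsid, freq_kg, freq_evs, sift, polyphen, phylop,
                        phastcons, coding_change, segdup, min_depth)))
  if (length(chrom) == 0) n <- 0L
  v <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    rsid = rep_len(as.character(rsid), n), ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    carriers = rep_len(as.character(carriers), n),
    freq_kg = rep_len(as.numeric(freq_kg), n),
    freq_evs = rep_len(as.numeric(freq_evs), n),
    gene = rep_len(as.character(gene), n),
    func_class = rep_len(as.character(func_class), n),
    coding_change = rep_len(as.character(coding_change), n),
    phylop = rep_len(as.numeric(phylop), n),
    phastcons = rep_len(as.numeric(phastcons), n),
    sift = rep_len(as.numeric(sift), n),
    polyphen = rep_len(as.numeric(polyphen), n),
    segdup = rep_len(as.logical(segdup), n),
    min_depth = rep_len(as.integer(min_depth), n),
    stringsAsFactors = FALSE
  )
  validate_variants(v)
  class(v) <- c("sli_variants", "data.frame")
  v
}

#' Validate an annotated-variant table
#'
#' Checks the type-level invariants: positions are positive, `ref != alt`,
#' frequencies and bounded scores lie in `[0, 1]` where present, and the
#' functional class is one of the recognised enumeration values.
#'
#' @param v Variant table.
#' @param where Optional label (e.g. file path) used in error messages.
#' @return `v`, invisibly.
#' @export
validate_variants <- function(v, where = "variant table") {
  bad_line <- function(i, msg) {
    stop(sprintf("%s, record %d: %s", where, i, msg), call. = FALSE)
  }
  for (i in seq_len(nrow(v))) {
    if (is.na(v$pos[i]) || v$pos[i] < 1L) bad_line(i, "pos must be >= 1")
    if (!is.na(v$ref[i]) && !is.na(v$alt[i]) && v$ref[i] == v$alt[i]) {
      bad_line(i, "ref and alt alleles are identical")
    }
    if (!v$func_class[i] %in% .FUNC_CLASSES) {
      bad_line(i, sprintf("unknown func_class '%s'", v$func_class[i]))
    }
  }
  for (col in c("freq_kg", "freq_evs", "sift", "polyphen", "phastcons")) {
    x <- v[[col]]
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad)) {
      bad_line(bad[1], sprintf("%s = %g outside [0, 1]", col, x[bad[1]]))
    }
  }
  bad <- which(!is.na(v$min_depth) & v$min_depth < 0L)
  if (length(bad)) bad_line(bad[1], "negative min_depth")
  invisible(v)
}

#' Expand the carrier column into (variant, proband) pairs
#'
#' The dialect stores multi-proband carrier cells comma-separated in one row
#' (e.g. the shared candidate-gene variant carried by probands 27, 36 and 39);
#' internally each (variant, proband) pair is one record.
#'
#' @param v Variant table with a `carriers` column.
#' @return `data.frame` with one row per (variant, carrier) pair: all variant
#'   columns plus `proband` and `key`.
#' @export
expand_carriers <- function(v) {
  if (!nrow(v)) {
    out <- v
    out$proband <- character(0)
    out$key <- character(0)
    return(out)
  }
  carr <- strsplit(ifelse(is.na(v$carriers), "", v$carriers), ",")
  carr <- lapply(carr, function(x) trimws(x[nzchar(trimws(x))]))
  n <- lengths(carr)
  out <- v[rep(seq_len(nrow(v)), n), , drop = FALSE]
  out$proband <- unlist(carr, use.names = FALSE)
  if (is.null(out$proband)) out$proband <- character(0)
  out$key <- variant_key(out)
  rownames(out) <- NULL
  out
}

#' @export
print.sli_variants <- function(x, ...) {
  cat(sprintf("Annotated variant table: %d variants, %d genes\n",
              nrow(x), length(unique(x$gene))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
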