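#' @title Variant expression-filter cascade
#'
#' @description
#' Somatic variants called against the tumor exome are winnowed in three
#' tiers before peptide design: (1) keep variants in coding sequence;
#' (2) keep variants confirmed as expressed by at least one tumor-RNA
#' read carrying the variant base; (3) keep variants passing a strict
#' expression threshold of 20% variant allele frequency (VAF) and at
#' least 10 variant-supporting RNA reads. [cascadeSummary()] reports the
#' count surviving each tier.
#'
#' Variant tables are plain `data.frame`s with the canonical columns
#' `variant_id, chrom, pos, ref, alt, class, gene, transcript,
#' protein_pos, aa_ref, aa_alt, dna_alt, dna_ref, rna_alt, rna_depth`
#' (see [readVariantTable()]).
#'
#' @param variants Variant `data.frame` (canonical columns).
#' @param coding_classes Consequence classes counted as coding; defaults
#'   to every class except `noncoding` (see [codingClasses()]).
#' @param min_alt_reads Minimum variant-supporting RNA reads for the
#'   expressed tier (default 1).
#' @param min_vaf Minimum RNA VAF for the strict tier, in `[0, 1]`
#'   (default 0.20); inclusive.
#' @param min_reads Minimum RNA read count for the strict tier (default
#'   10); inclusive. Interpreted per `strict_reads_mode`.
#' @param strict_reads_mode Either `"alt"` (default; `min_reads` applies
#'   to variant-supporting RNA reads) or `"depth"` (applies to total RNA
#'   depth at the site).
#' @return For the filters, the retained rows of `variants` in input
#'   order; for [cascadeSummary()], a [CascadeSummary-class].
#' @name variantFilters
NULL

VARIANT_COLUMNS <- c("variant_id", "chrom", "pos", "ref", "alt", "class",
                     "gene", "transcript", "protein_pos", "aa_ref",
                     "aa_alt", "dna_alt", "dna_ref", "rna_alt",
                     "rna_depth")

#' Validate a variant table
#'
#' Checks the canonical column set and the row-level invariants: 1-based
#' positions, known consequence classes, non-negative read counts with
#' `rna_alt <= rna_depth`, `protein_pos` present exactly for coding
#' classes, and `aa_ref`/`aa_alt` present exactly for protein-altering
#' classes. Errors name the offending `variant_id`s.
#'
#' @param variants Variant `data.frame`.
#' @return `variants`, invisibly, if valid.
#' @export
validateVariantTable <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols))
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(variants)) return(invisible(variants))
  id <- as.character(variants$variant_id)
  bad <- function(which, what) {
    if (any(which))
      stop(what, " for variant(s): ",
           paste(utils::head(id[which], 5L), collapse = ", "))
  }
  bad(is.na(id) | !nzchar(id), "missing variant_id")
  if (anyDuplicated(id))
    stop("duplicated variant_id(s): ",
         paste(unique(id[duplicated(id)])[1:min(5, sum(duplicated(id)))],
               collapse = ", "))
  bad(is.na(variants$pos) | variants$pos < 1, "position must be >= 1")
  bad(is.na(variants$class), "missing variant class")
  bad(!is.na(variants$class) & !variants$class %in% variantClasses(),
      "unknown variant class")
  bad(is.na(variants$rna_alt) | variants$rna_alt < 0,
      "rna_alt must be a non-negative count")
  bad(is.na(variants$rna_depth) | variants$rna_depth < 0,
      "rna_depth must be a non-negative count")
  bad(variants$rna_alt > variants$rna_depth,
      "rna_alt exceeds rna_depth")
  coding <- variants$class %in% codingClasses()
  bad(coding & is.na(variants$protein_pos),
      "coding variant lacks protein_pos")
  bad(!coding & !is.na(variants$protein_pos),
      "noncoding variant carries protein_pos")
  altering <- variants$class %in% proteinAlteringClasses()
  bad(altering & (is.na(variants$aa_ref) | is.na(variants$aa_alt)),
      "protein-altering variant lacks aa_ref/aa_alt")
  invisible(variants)
}

#' @rdname variantFilters
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1, tier_counts = c(40, 24, 12, 5),
#'                         n_proteins = 6)
#' prot <- genProteome(cfg)
#' vt <- genVariantTable(cfg, prot)$variants
#' tierCounts(cascadeSummary(vt))
filterCoding <- function(variants, coding_classes = codingClasses()) {
  stopifnot(is.data.frame(variants))
  if (!nrow(variants)) return(variants)
  if (!"class" %in% names(variants))
    stop("variant table lacks a 'class' column")
  miss <- is.na(variants$class)
  if (any(miss))
    stop("missing variant_class for variant(s): ",
         paste(utils::head(as.character(variants$variant_id)[miss], 5L),
               collapse = ", "))
  variants[variants$class %in% coding_classes, , drop = FALSE]
}

#' @rdname variantFilters
#' @export
filterRnaExpressed <- function(variants, min_alt_reads = 1L) {
  stopifnot(is.data.frame(variants))
  if (length(min_alt_reads) != 1L || is.na(min_alt_reads) ||
      min_alt_reads < 0)
    stop("min_alt_reads must be a single non-negative integer")
  if (!nrow(variants)) return(variants)
  if (anyNA(variants$rna_alt))
    stop("rna_alt reads missing for variant(s): ",
         paste(utils::head(as.character(
           variants$variant_id)[is.na(variants$rna_alt)], 5L),
           collapse = ", "))
  variants[variants$rna_alt >= min_alt_reads, , drop = FALSE]
}

#' @rdname variantFilters
#' @export
filterStrict <- function(variants, min_vaf = 0.20, min_reads = 10L,
                         strict_reads_mode = c("alt", "depth")) {
  stopifnot(is.data.frame(variants))
  strict_reads_mode <- match.arg(strict_reads_mode)
  if (length(min_vaf) != 1L || is.na(min_vaf) || min_vaf < 0 || min_vaf > 1)
    stop("min_vaf must be a single value in [0, 1]")
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 0)
    stop("min_reads must be a single non-negative integer")
  if (!nrow(variants)) return(variants)
  # zero-depth sites have undefined VAF: they fail the tier, not error
  depth_ok <- !is.na(variants$rna_depth) & variants$rna_depth > 0
  vaf <- ifelse(depth_ok, variants$rna_alt / variants$rna_depth, NA_real_)
  reads <- if (strict_reads_mode == "alt") variants$rna_alt
           else variants$rna_depth
  keep <- depth_ok & vaf >= min_vaf & reads >= min_reads
  variants[keep %in% TRUE, , drop = FALSE]
}

#' @rdname variantFilters
#' @export
cascadeSummary <- function(variants, coding_classes = codingClasses(),
                           min_alt_reads = 1L, min_vaf = 0.20,
                           min_reads = 10L,
                           strict_reads_mode = c("alt", "depth")) {
  stopifnot(is.data.frame(variants))
  strict_reads_mode <- match.arg(strict_reads_mode)
  coding <- filterCoding(variants, coding_classes)
  expressed <- filterRnaExpressed(coding, min_alt_reads)
  strict <- filterStrict(expressed, min_vaf, min_reads, strict_reads_mode)
  new("CascadeSummary", n_total = nrow(variants), n_coding = nrow(coding),
      n_expressed = nrow(expressed), n_strict = nrow(strict))
}

#' Read and write canonical variant tables
#'
#' Tab-delimited with header `variant_id, chrom, pos, ref, alt, class,
#' gene, transcript, protein_pos, aa_ref, aa_alt, dna_alt, dna_ref,
#' rna_alt, rna_depth`; `NA` marks absent coding fields.
#'
#' @param file Path to a tab-delimited variant table.
#' @param variants Variant `data.frame` to write.
#' @param validate Validate on read/write (default `TRUE`).
#' @return `readVariantTable()` returns the validated `data.frame`;
#'   `writeVariantTable()` returns `file` invisibly.
#' @export
readVariantTable <- function(file, validate = TRUE) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   colClasses = c(variant_id = "character",
                                  chrom = "character", ref = "character",
                                  alt = "character", class = "character",
                                  gene = "character",
                                  transcript = "character",
                                  aa_ref = "character",
                                  aa_alt = "character"))
  if (validate) validateVariantTable(df)
  df
}

#' @rdname readVariantTable
#' @export
writeVariantTable <- function(variants, file, validate = TRUE) {
  if (validate) validateVariantTable(variants)
  write.table(variants[, VARIANT_COLUMNS, drop = FALSE], file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Import somatic variants from a VCF
#'
#' Builds a canonical variant table from a VCF 4.x file: tumor DNA
#' allele counts are taken from the per-sample `AD` genotype field, the
#' consequence class from a configured INFO key, and tumor RNA evidence
#' from a companion tab-delimited table keyed on `chrom:pos:ref:alt`
#' with columns `key, rna_alt, rna_depth`. Optional INFO keys supply
#' gene, transcript, protein position, and amino acids.
#'
#' Requires the `VariantAnnotation` package.
#'
#' @param vcf_file Path to a VCF file.
#' @param rna_counts_file Path to the companion RNA-count table.
#' @param class_key INFO key holding the consequence class (default
#'   `"CLASS"`).
#' @param gene_key,transcript_key,protein_pos_key,aa_ref_key,aa_alt_key
#'   Optional INFO keys for coding annotation (default `"GENE"`,
#'   `"TRANSCRIPT"`, `"PPOS"`, `"AAREF"`, `"AAALT"`; absent keys yield
#'   `NA`).
#' @param sample Sample index or name whose `AD` supplies DNA counts
#'   (default 1).
#' @return A validated canonical variant `data.frame`.
#' @export
readVcfVariants <- function(vcf_file, rna_counts_file,
                            class_key = "CLASS", gene_key = "GENE",
                            transcript_key = "TRANSCRIPT",
                            protein_pos_key = "PPOS",
                            aa_ref_key = "AAREF", aa_alt_key = "AAALT",
                            sample = 1L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVcfVariants() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(vcf_file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(key, as = as.character) {
    if (!is.null(key) && key %in% colnames(info)) {
      v <- info[[key]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(x)
          if (length(x)) as.character(x[[1L]]) else NA_character_,
          character(1L))
      as(v)
    } else rep(as(NA), n)
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the per-sample AD genotype field")
  ad_s <- ad[, sample]
  dna_ref <- vapply(ad_s, function(x) as.integer(x[1L]), integer(1L))
  dna_alt <- vapply(ad_s, function(x)
    if (length(x) >= 2L) as.integer(x[2L]) else NA_integer_, integer(1L))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)), function(x)
    as.character(x[[1L]]), character(1L))
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  rna <- read.delim(rna_counts_file, stringsAsFactors = FALSE)
  need <- c("key", "rna_alt", "rna_depth")
  if (!all(need %in% names(rna)))
    stop("RNA companion table must have columns: ",
         paste(need, collapse = ", "))
  idx <- match(key, rna$key)
  if (anyNA(idx))
    stop("no RNA counts for variant key(s): ",
         paste(utils::head(key[is.na(idx)], 5L), collapse = ", "))
  df <- data.frame(
    variant_id = if (!is.null(rownames(vcf)) &&
                     !anyDuplicated(rownames(vcf))) rownames(vcf)
                 else key,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    class = getInfo(class_key),
    gene = getInfo(gene_key),
    transcript = getInfo(transcript_key),
    protein_pos = getInfo(protein_pos_key,
                          as = function(x) as.integer(as.character(x))),
    aa_ref = getInfo(aa_ref_key),
    aa_alt = getInfo(aa_alt_key),
    dna_alt = dna_alt, dna_ref = dna_ref,
    rna_alt = as.integer(rna$rna_alt[idx]),
    rna_depth = as.integer(rna$rna_depth[idx]),
    stringsAsFactors = FALSE, row.names = NULL)
  validateVariantTable(df)
  df
}
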