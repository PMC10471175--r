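#' PeptideSet: designed peptides with anchor metadata
#'
#' An [Biostrings::AAStringSet] subclass holding designed long peptides
#' or epitope candidates. Element names are peptide ids; the elementwise
#' metadata (`mcols`) carries, for every peptide, the mutation it
#' represents, the gene symbol, the isoform label, the realized and
#' requested anchor positions (1-based index of the mutated residue
#' within the peptide), whether the sequence is the mutant or the
#' wild-type counterpart, the 1-based start of the peptide in its source
#' protein, and a flag marking peptides truncated because the source
#' protein was shorter than the requested length.
#'
#' @slot NULL inherits all slots from `AAStringSet`.
#' @seealso [designLongPeptides()], [peptideManifest()]
#' @export
setClass("PeptideSet", contains = "AAStringSet")

.PEPTIDE_MCOLS <- c("mutation_id", "gene_symbol", "isoform_label",
                    "anchor", "requested_anchor", "is_mutant",
                    "protein_start", "truncated")

setValidity("PeptideSet", function(object) {
  msg <- character()
  mc <- mcols(object)
  if (is.null(mc) || !all(.PEPTIDE_MCOLS %in% colnames(mc)))
    return(paste("mcols must contain columns:",
                 paste(.PEPTIDE_MCOLS, collapse = ", ")))
  if (length(object)) {
    if (is.null(names(object)) || anyNA(names(object)))
      msg <- c(msg, "peptide ids (names) must be present")
    else if (anyDuplicated(names(object)))
      msg <- c(msg, "peptide ids must be unique")
    a <- mc$anchor
    if (anyNA(a) || any(a < 1L) || any(a > width(object)))
      msg <- c(msg, "anchor must lie within [1, peptide length]")
    if (!is.logical(mc$is_mutant) || anyNA(mc$is_mutant))
      msg <- c(msg, "is_mutant must be TRUE/FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideSet
#'
#' @param sequences Character vector or `AAStringSet` of peptide
#'   sequences.
#' @param peptide_id Unique peptide identifiers (names of the set).
#' @param mutation_id Mutation each peptide represents.
#' @param gene_symbol,isoform_label Optional annotation (recycled).
#' @param anchor Realized 1-based position of the mutated residue within
#'   each peptide.
#' @param requested_anchor Anchor position that was requested before any
#'   terminal shift (defaults to `anchor`).
#' @param is_mutant Logical; `TRUE` for mutant sequences, `FALSE` for
#'   wild-type counterparts.
#' @param protein_start 1-based start of the peptide window in its
#'   source protein.
#' @param truncated Logical; `TRUE` when the source protein was shorter
#'   than the requested peptide length.
#' @return A [PeptideSet-class] object.
#' @export
#' @examples
#' PeptideSet("ACDEFGHIKL", peptide_id = "Mut_1.a6", mutation_id = "M1",
#'            anchor = 6L, is_mutant = TRUE, protein_start = 1L)
PeptideSet <- function(sequences, peptide_id = names(sequences),
                       mutation_id, gene_symbol = NA_character_,
                       isoform_label = NA_character_, anchor,
                       requested_anchor = anchor, is_mutant,
                       protein_start, truncated = FALSE) {
  x <- AAStringSet(as.character(sequences))
  n <- length(x)
  names(x) <- as.character(peptide_id)
  mcols(x) <- DataFrame(
    mutation_id = rep_len(as.character(mutation_id), n),
    gene_symbol = rep_len(as.character(gene_symbol), n),
    isoform_label = rep_len(as.character(isoform_label), n),
    anchor = rep_len(as.integer(anchor), n),
    requested_anchor = rep_len(as.integer(requested_anchor), n),
    is_mutant = rep_len(as.logical(is_mutant), n),
    protein_start = rep_len(as.integer(protein_start), n),
    truncated = rep_len(as.logical(truncated), n))
  new("PeptideSet", x)
}

#' @describeIn PeptideSet-class peptide identifiers.
#' @param x,object A `PeptideSet`.
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname PeptideSet-class
#' @export
setMethod("peptideIds", "PeptideSet", function(x) names(x))

#' @describeIn PeptideSet-class mutation ids, one per peptide.
#' @export
setGeneric("mutationIds", function(x) standardGeneric("mutationIds"))

#' @rdname PeptideSet-class
#' @export
setMethod("mutationIds", "PeptideSet", function(x) mcols(x)$mutation_id)

#' @describeIn PeptideSet-class logical vector marking mutant sequences.
#' @export
setGeneric("isMutant", function(x) standardGeneric("isMutant"))

#' @rdname PeptideSet-class
#' @export
setMethod("isMutant", "PeptideSet", function(x) mcols(x)$is_mutant)

#' @describeIn PeptideSet-class realized anchor positions.
#' @export
setGeneric("anchorPositions", function(x) standardGeneric("anchorPositions"))

#' @rdname PeptideSet-class
#' @export
setMethod("anchorPositions", "PeptideSet", function(x) mcols(x)$anchor)

#' Peptide manifest as a data.frame
#'
#' Flattens a [PeptideSet-class] into the tab-delimited manifest shape
#' used on disk: one row per peptide with its sequence and all anchor
#' metadata.
#'
#' @param x A `PeptideSet`.
#' @return A `data.frame` with columns `peptide_id`, `mutation_id`,
#'   `gene_symbol`, `isoform_label`, `sequence`, `anchor`,
#'   `requested_anchor`, `is_mutant`, `protein_start`, `truncated`.
#' @export
setGeneric("peptideManifest", function(x) standardGeneric("peptideManifest"))

#' @rdname peptideManifest
#' @export
setMethod("peptideManifest", "PeptideSet", function(x) {
  mc <- as.data.frame(mcols(x))
  data.frame(peptide_id = names(x),
             mutation_id = mc$mutation_id,
             gene_symbol = mc$gene_symbol,
             isoform_label = mc$isoform_label,
             sequence = as.character(x),
             anchor = mc$anchor,
             requested_anchor = mc$requested_anchor,
             is_mutant = mc$is_mutant,
             protein_start = mc$protein_start,
             truncated = mc$truncated,
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "PeptideSet", function(object) {
  cat("PeptideSet with", length(object), "peptides (",
      sum(mcols(object)$is_mutant), "mutant,",
      sum(!mcols(object)$is_mutant), "wild-type )\n")
  if (length(object)) {
    mc <- mcols(object)
    n <- min(6L, length(object))
    df <- data.frame(peptide_id = names(object)[seq_len(n)],
                     sequence = as.character(object)[seq_len(n)],
                     anchor = mc$anchor[seq_len(n)],
                     is_mutant = mc$is_mutant[seq_len(n)])
    print(df, row.names = FALSE)
    if (length(object) > n) cat("...", length(object) - n, "more\n")
  }
  invisible(NULL)
})

#' CascadeSummary: per-tier variant counts
#'
#' Counts of variants surviving each tier of the expression-filter
#' cascade: all variants, those in coding sequence, those with RNA
#' expression evidence, and those passing the strict VAF/read
#' thresholds. Counts are non-increasing across tiers.
#'
#' @slot n_total,n_coding,n_expressed,n_strict Integer tier counts.
#' @seealso [cascadeSummary()]
#' @export
setClass("CascadeSummary",
         representation(n_total = "integer", n_coding = "integer",
                        n_expressed = "integer", n_strict = "integer"))

setValidity("CascadeSummary", function(object) {
  n <- tierCounts(object)
  if (anyNA(n) || any(n < 0L))
    return("tier counts must be non-negative")
  if (is.unsorted(rev(n)))
    return("tier counts must be non-increasing: total >= coding >= expressed >= strict")
  TRUE
})

#' @describeIn CascadeSummary-class named integer vector of the four
#'   tier counts.
#' @param x,object A `CascadeSummary`.
#' @export
setGeneric("tierCounts", function(x) standardGeneric("tierCounts"))

#' @rdname CascadeSummary-class
#' @export
setMethod("tierCounts", "CascadeSummary", function(x)
  c(n_total = x@n_total, n_coding = x@n_coding,
    n_expressed = x@n_expressed, n_strict = x@n_strict))

setMethod("show", "CascadeSummary", function(object) {
  n <- tierCounts(object)
  cat("Variant expression-filter cascade\n")
  cat(sprintf("  total:     %d\n  coding:    %d\n  expressed: %d\n  strict:    %d\n",
              n[1L], n[2L], n[3L], n[4L]))
  invisible(NULL)
})

#' LinkedConstruct: tethered helper-effector peptide
#'
#' A covalently linked vaccine construct joining an MHC II helper
#' epitope to an MHC I effector (CTL) epitope through a short linker
#' (triple alanine by default). The combined sequence is always
#' helper + linker + effector.
#'
#' @slot helper,effector,linker,combined Character; component and
#'   combined amino-acid sequences.
#' @seealso [buildLinkedConstruct()]
#' @export
setClass("LinkedConstruct",
         representation(helper = "character", effector = "character",
                        linker = "character", combined = "character"))

setValidity("LinkedConstruct", function(object) {
  if (!nzchar(object@helper) || !nzchar(object@effector))
    return("helper and effector sequences must be non-empty")
  if (!identical(object@combined,
                 paste0(object@helper, object@linker, object@effector)))
    return("combined must equal helper + linker + effector")
  TRUE
})

setMethod("show", "LinkedConstruct", function(object) {
  cat("LinkedConstruct:", object@combined, "\n")
  cat(sprintf("  helper   %s (1-%d)\n", object@helper, nchar(object@helper)))
  if (nzchar(object@linker))
    cat(sprintf("  linker   %s\n", object@linker))
  cat(sprintf("  effector %s (%d-%d)\n", object@effector,
              nchar(object@helper) + nchar(object@linker) + 1L,
              nchar(object@combined)))
  invisible(NULL)
})

#' @describeIn LinkedConstruct-class combined amino-acid sequence.
#' @param x,object A `LinkedConstruct`.
#' @export
setGeneric("combinedSequence", function(x) standardGeneric("combinedSequence"))

#' @rdname LinkedConstruct-class
#' @export
setMethod("combinedSequence", "LinkedConstruct", function(x) x@combined)
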