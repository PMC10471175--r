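#' Apply a missense substitution to a protein sequence
#'
#' Substitutes a single residue, guarding against transcript/annotation
#' drift: the residue observed at `protein_position` must equal
#' `aa_ref`, otherwise an error reports expected vs observed.
#'
#' @param sequence Amino-acid string (or `AAString`/length-1
#'   `AAStringSet`) of the reference protein.
#' @param protein_position 1-based residue index of the substitution.
#' @param aa_ref,aa_alt Single-letter reference and alternate residues.
#' @return The mutated sequence as a character scalar.
#' @export
#' @examples
#' applyMissense("ACDEF", 3, "D", "N")  # "ACNEF"
applyMissense <- function(sequence, protein_position, aa_ref, aa_alt) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  protein_position <- as.integer(protein_position)
  if (is.na(protein_position) || protein_position < 1L ||
      protein_position > nchar(sequence))
    stop("protein_position ", protein_position,
         " outside protein of length ", nchar(sequence))
  observed <- substr(sequence, protein_position, protein_position)
  if (!identical(observed, as.character(aa_ref)))
    stop("reference residue mismatch at position ", protein_position,
         ": expected ", aa_ref, ", observed ", observed)
  substr(sequence, protein_position, protein_position) <-
    as.character(aa_alt)
  sequence
}

# Choose the peptide window [start, end] of length `len` placing the
# mutated residue m at anchor position a, shifting minimally when the
# window would overrun a protein terminus. Returns start/end and
# truncation flag; the realized anchor is m - start + 1.
.peptideWindow <- function(m, a, len, protein_len) {
  if (protein_len < len) {
    # protein itself shorter than the requested peptide: emit it whole
    return(list(start = 1L, end = protein_len, truncated = TRUE))
  }
  start <- m - a + 1L
  if (start < 1L) start <- 1L
  end <- start + len - 1L
  if (end > protein_len) {
    end <- protein_len
    start <- end - len + 1L
  }
  list(start = start, end = end, truncated = FALSE)
}

#' Design mutant/wild-type long-peptide pairs
#'
#' For each requested anchor position `a`, emits a mutant peptide of
#' `length` residues spanning the mutant protein so that the mutated
#' residue sits at position `a` of the peptide, flanked by wild-type
#' sequence, plus the wild-type counterpart over the same window of the
#' reference protein. Near a protein terminus the window is shifted
#' minimally to fit (the realized anchor is recomputed and recorded);
#' windows that coincide after shifting are emitted once. Proteins
#' shorter than `length` yield a single truncated peptide covering the
#' whole protein, flagged in the manifest.
#'
#' @param mutant_protein,reference_protein Amino-acid strings of the
#'   mutant and reference proteins (equal length for missense; for
#'   indels supply the precomputed mutant product and the anchor is the
#'   first altered residue).
#' @param mut_residue_index 1-based index of the mutated residue in the
#'   mutant protein.
#' @param mutation_id Identifier of the mutation (used in peptide ids
#'   `Mut_<id>.a<anchor>` / `WT_<id>.a<anchor>`).
#' @param anchors Requested anchor positions (default `c(6, 15)`).
#' @param length Peptide length (default 20).
#' @param gene_symbol,isoform_label Optional annotation carried into the
#'   manifest.
#' @return A [PeptideSet-class] with one mutant and one wild-type
#'   peptide per unique realized window.
#' @export
#' @examples
#' mut <- paste(rep("A", 40), collapse = ""); substr(mut, 20, 20) <- "Q"
#' wt <- paste(rep("A", 40), collapse = "")
#' designLongPeptides(mut, wt, 20, mutation_id = "demo")
designLongPeptides <- function(mutant_protein, reference_protein,
                               mut_residue_index, mutation_id,
                               anchors = c(6L, 15L), length = 20L,
                               gene_symbol = NA_character_,
                               isoform_label = NA_character_) {
  mutant_protein <- as.character(mutant_protein)
  reference_protein <- as.character(reference_protein)
  length <- as.integer(length)
  anchors <- as.integer(anchors)
  m <- as.integer(mut_residue_index)
  plen <- nchar(mutant_protein)
  stopifnot(length >= 1L, length(anchors) >= 1L)
  if (any(is.na(anchors)) || any(anchors < 1L) || any(anchors > length))
    stop("anchors must lie in [1, length]")
  if (is.na(m) || m < 1L || m > plen)
    stop("mut_residue_index ", m, " outside mutant protein of length ",
         plen)
  if (nchar(reference_protein) < 1L)
    stop("reference protein must be non-empty")

  wins <- lapply(anchors, .peptideWindow, m = m, len = length,
                 protein_len = plen)
  starts <- vapply(wins, `[[`, integer(1L), "start")
  keep <- !duplicated(starts)
  wins <- wins[keep]
  anchors <- anchors[keep]
  if (any(vapply(wins, `[[`, logical(1L), "truncated")))
    warning("protein '", mutation_id, "' shorter than requested peptide ",
            "length; peptide truncated to the full protein")

  seqs <- ids <- character(0)
  anc <- req <- pstart <- integer(0)
  ismut <- trunc_flag <- logical(0)
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    realized <- m - w$start + 1L
    mut_seq <- substr(mutant_protein, w$start, w$end)
    wt_end <- min(w$end, nchar(reference_protein))
    wt_seq <- substr(reference_protein, w$start, wt_end)
    seqs <- c(seqs, mut_seq, wt_seq)
    ids <- c(ids, sprintf("Mut_%s.a%d", mutation_id, anchors[i]),
             sprintf("WT_%s.a%d", mutation_id, anchors[i]))
    anc <- c(anc, realized, realized)
    req <- c(req, anchors[i], anchors[i])
    pstart <- c(pstart, w$start, w$start)
    ismut <- c(ismut, TRUE, FALSE)
    trunc_flag <- c(trunc_flag, w$truncated, w$truncated)
  }
  PeptideSet(seqs, peptide_id = ids, mutation_id = mutation_id,
             gene_symbol = gene_symbol, isoform_label = isoform_label,
             anchor = anc, requested_anchor = req, is_mutant = ismut,
             protein_start = pstart, truncated = trunc_flag)
}

#' Design peptides for every design-eligible variant in a table
#'
#' Runs [applyMissense()] + [designLongPeptides()] for each missense
#' variant, looking up the source protein in `proteome` by
#' `transcript`. Variants of other classes are skipped with a message
#' (indel products must be designed directly from a precomputed mutant
#' protein via [designLongPeptides()]).
#'
#' @param variants Variant `data.frame` (normally the strict tier).
#' @param proteome Named `AAStringSet` (names are transcript ids); may
#'   carry `gene_symbol` and `isoform_label` metadata columns.
#' @param anchors,length Passed to [designLongPeptides()].
#' @return A combined [PeptideSet-class].
#' @export
designFromVariants <- function(variants, proteome, anchors = c(6L, 15L),
                               length = 20L) {
  stopifnot(is.data.frame(variants), is(proteome, "AAStringSet"))
  eligible <- variants$class == "missense"
  skipped <- sum(!eligible)
  if (skipped)
    message("skipping ", skipped,
            " non-missense variant(s); supply precomputed mutant ",
            "proteins to designLongPeptides() for indels")
  variants <- variants[eligible, , drop = FALSE]
  if (!nrow(variants)) return(emptyPeptideSet())
  mc <- mcols(proteome)
  sets <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tx <- as.character(v$transcript)
    if (!tx %in% names(proteome))
      stop("transcript ", tx, " (variant ", v$variant_id,
           ") not found in proteome")
    ref_seq <- as.character(proteome[[tx]])
    mut_seq <- applyMissense(ref_seq, v$protein_pos, v$aa_ref, v$aa_alt)
    iso <- if (!is.null(mc$isoform_label))
      mc$isoform_label[match(tx, names(proteome))] else NA_character_
    sets[[i]] <- designLongPeptides(
      mut_seq, ref_seq, v$protein_pos, mutation_id = v$variant_id,
      anchors = anchors, length = length, gene_symbol = v$gene,
      isoform_label = iso)
  }
  do.call(c, sets)
}

emptyPeptideSet <- function() {
  PeptideSet(character(0), peptide_id = character(0),
             mutation_id = character(0), anchor = integer(0),
             is_mutant = logical(0), protein_start = integer(0))
}

#' Enumerate minimal-epitope tiles of a long peptide
#'
#' Emits every contiguous window of each requested length that contains
#' the parent peptide's anchor (mutated) residue — the candidate minimal
#' epitopes for MHC I (typically 10-mers) and MHC II (15-mers)
#' restriction mapping. Tile ids are `<parent>.k` numbered with lengths
#' descending and offsets ascending.
#'
#' @param parent A length-1 [PeptideSet-class] (or a character sequence,
#'   in which case `anchor` and `parent_id` must be given).
#' @param lengths Tile lengths, each `<=` the parent length (default
#'   `c(15, 10)`).
#' @param anchor,parent_id Anchor position and id when `parent` is a
#'   bare sequence.
#' @return `data.frame` with columns `tile_id, parent_peptide_id,
#'   offset, length, sequence`.
#' @export
#' @examples
#' p <- PeptideSet("ACDEFGHIKLMNPQRSTVWY", peptide_id = "Mut_x.a15",
#'                 mutation_id = "x", anchor = 15L, is_mutant = TRUE,
#'                 protein_start = 1L)
#' tileMinimalEpitopes(p, lengths = 10)
tileMinimalEpitopes <- function(parent, lengths = c(15L, 10L),
                                anchor = NULL, parent_id = NULL) {
  if (is(parent, "PeptideSet")) {
    stopifnot(length(parent) == 1L)
    seqchr <- as.character(parent)[[1L]]
    anchor <- mcols(parent)$anchor[1L]
    parent_id <- names(parent)[1L]
  } else {
    seqchr <- as.character(parent)
    stopifnot(length(seqchr) == 1L, !is.null(anchor), !is.null(parent_id))
  }
  plen <- nchar(seqchr)
  anchor <- as.integer(anchor)
  lengths <- sort(unique(as.integer(lengths)), decreasing = TRUE)
  if (any(lengths < 1L) || any(lengths > plen))
    stop("tile lengths must lie in [1, parent length]")
  stopifnot(anchor >= 1L, anchor <= plen)
  out <- list()
  for (L in lengths) {
    offsets <- seq.int(max(1L, anchor - L + 1L), min(plen - L + 1L, anchor))
    out[[as.character(L)]] <- data.frame(
      parent_peptide_id = parent_id, offset = offsets, length = L,
      sequence = substring(seqchr, offsets, offsets + L - 1L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- data.frame(tile_id = sprintf("%s.%d", parent_id,
                                      seq_len(nrow(res))),
                    res, stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Build a tethered helper-effector construct
#'
#' Covalently links an MHC II helper epitope to an MHC I effector
#' epitope through a short linker (triple alanine, `"AAA"`, by default),
#' the configuration found to confer superior protection over untethered
#' peptide mixtures.
#'
#' @param helper,effector Non-empty amino-acid sequences.
#' @param linker Linker sequence (default `"AAA"`; may be empty).
#' @return A [LinkedConstruct-class].
#' @export
#' @examples
#' buildLinkedConstruct("HHHHH", "EEEEE")
buildLinkedConstruct <- function(helper, effector, linker = "AAA") {
  helper <- as.character(helper); effector <- as.character(effector)
  linker <- as.character(linker)
  if (length(helper) != 1L || !nzchar(helper))
    stop("helper sequence must be a non-empty string")
  if (length(effector) != 1L || !nzchar(effector))
    stop("effector sequence must be a non-empty string")
  new("LinkedConstruct", helper = helper, effector = effector,
      linker = linker, combined = paste0(helper, linker, effector))
}

#' Read and write peptide FASTA and manifests
#'
#' FASTA description lines carry
#' `mutation_id|anchor|is_mutant|protein_start` after the peptide id;
#' the manifest is the tab-delimited flattening of the full metadata
#' (see [peptideManifest()]).
#'
#' @param x A [PeptideSet-class].
#' @param file Output/input path.
#' @return Readers return a `PeptideSet` / manifest `data.frame`;
#'   writers return `file` invisibly.
#' @export
writePeptideFasta <- function(x, file) {
  stopifnot(is(x, "PeptideSet"))
  mc <- mcols(x)
  out <- AAStringSet(as.character(x))
  names(out) <- sprintf("%s %s|%d|%s|%d", names(x), mc$mutation_id,
                        mc$anchor, ifelse(mc$is_mutant, "mut", "wt"),
                        mc$protein_start)
  writeXStringSet(out, file)
  invisible(file)
}

#' @rdname writePeptideFasta
#' @export
readPeptideFasta <- function(file) {
  raw <- readAAStringSet(file)
  parts <- strsplit(names(raw), " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  meta <- strsplit(vapply(parts, function(p)
    if (length(p) >= 2L) p[[2L]] else "NA|NA|NA|NA", character(1L)),
    "|", fixed = TRUE)
  PeptideSet(as.character(raw), peptide_id = ids,
             mutation_id = vapply(meta, `[[`, character(1L), 1L),
             anchor = as.integer(vapply(meta, `[[`, character(1L), 2L)),
             is_mutant = vapply(meta, `[[`, character(1L), 3L) == "mut",
             protein_start = as.integer(
               vapply(meta, `[[`, character(1L), 4L)))
}

#' @rdname writePeptideFasta
#' @export
writePeptideManifest <- function(x, file) {
  write.table(peptideManifest(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writePeptideFasta
#' @export
readPeptideManifest <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}
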