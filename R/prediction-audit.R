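#' Partition predicted MHC binders at an affinity cutoff
#'
#' Splits a table of predicted peptide-MHC binding affinities at the
#' conventional screening cutoff (500 nM IC50 by default). Lower IC50
#' means stronger predicted binding; records at or below the cutoff
#' pass. Both partitions preserve input order.
#'
#' @param records `data.frame` of predictions with columns
#'   `peptide_id, sequence, allele, ic50_nm` (the shape of IEDB
#'   NetMHCpan tabular output after column selection); `ic50_nm` must
#'   be positive.
#' @param cutoff_nm Positive affinity cutoff in nM (default 500).
#' @return List with elements `pass` and `fail`, each a subset of
#'   `records`.
#' @export
#' @examples
#' rec <- data.frame(peptide_id = c("a", "b"),
#'                   sequence = c("AAAAAAAAAA", "CCCCCCCCCC"),
#'                   allele = "H-2Kk", ic50_nm = c(250.9, 4988.7))
#' applyAffinityCutoff(rec)$pass$peptide_id
applyAffinityCutoff <- function(records, cutoff_nm = 500) {
  stopifnot(is.data.frame(records), "ic50_nm" %in% names(records))
  if (length(cutoff_nm) != 1L || is.na(cutoff_nm) || cutoff_nm <= 0)
    stop("cutoff_nm must be a single positive value")
  bad <- is.na(records$ic50_nm) | records$ic50_nm <= 0
  if (any(bad))
    stop("non-positive IC50 for record(s): ",
         paste(utils::head(as.character(records$peptide_id)[bad], 5L),
               collapse = ", "))
  keep <- records$ic50_nm <= cutoff_nm
  list(pass = records[keep, , drop = FALSE],
       fail = records[!keep, , drop = FALSE])
}

#' Efficiency of an affinity cutoff at capturing validated epitopes
#'
#' Given peptides functionally validated as immunoreactive (e.g. by
#' ELISPOT) and their predicted IC50 affinities, reports what fraction
#' the standard cutoff would have retained: 100 x (validated records
#' passing the cutoff) / (validated records). The reported percentage
#' is truncated to a whole percent (so 2 of 3 reports 66); the exact
#' fraction is returned alongside.
#'
#' @param validated_ids Non-empty character vector of validated peptide
#'   ids; each must have exactly one record in `records`.
#' @param records Prediction table (see [applyAffinityCutoff()]).
#' @param cutoff_nm Affinity cutoff in nM (default 500, inclusive).
#' @return List with `percent` (integer, truncated), `fraction`
#'   (exact), `n_validated`, and `n_pass`.
#' @export
#' @examples
#' rec <- data.frame(peptide_id = c("Mut_48.10", "Mut_72", "Mut_73"),
#'                   sequence = NA, allele = "H-2Kk",
#'                   ic50_nm = c(4988.7, 250.9, 250.9))
#' screeningEfficiency(rec$peptide_id, rec)$percent  # 66
screeningEfficiency <- function(validated_ids, records, cutoff_nm = 500) {
  validated_ids <- as.character(validated_ids)
  if (!length(validated_ids))
    stop("validated_ids must be non-empty")
  stopifnot(is.data.frame(records),
            all(c("peptide_id", "ic50_nm") %in% names(records)))
  validated_ids <- unique(validated_ids)
  missing <- setdiff(validated_ids, records$peptide_id)
  if (length(missing))
    stop("no prediction record for validated id(s): ",
         paste(missing, collapse = ", "))
  dup <- intersect(validated_ids,
                   records$peptide_id[duplicated(records$peptide_id)])
  if (length(dup))
    stop("multiple prediction records for validated id(s) (aggregate ",
         "upstream): ", paste(dup, collapse = ", "))
  sub <- records[records$peptide_id %in% validated_ids, , drop = FALSE]
  part <- applyAffinityCutoff(sub, cutoff_nm)
  frac <- nrow(part$pass) / nrow(sub)
  list(percent = as.integer(floor(frac * 100 + 1e-9)), fraction = frac,
       n_validated = nrow(sub), n_pass = nrow(part$pass))
}

#' Read a prediction table
#'
#' Tab-delimited with columns `peptide_id, sequence, allele, ic50_nm`.
#'
#' @param file Path.
#' @return A `data.frame`.
#' @export
readPredictionTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence", "allele", "ic50_nm")
  if (!all(need %in% names(df)))
    stop("prediction table must have columns: ",
         paste(need, collapse = ", "))
  df
}
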