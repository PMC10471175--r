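#' Assign peptides to screening pools
#'
#' Peptides are shuffled with a seeded permutation and dealt round-robin
#' into `n_pools` pools, so pool sizes differ by at most one and the
#' assignment is reproducible. With `group_by`, sibling peptides sharing
#' a group key (e.g. all peptides of one mutation) are kept in the same
#' pool by greedy smallest-pool placement of shuffled groups; pool sizes
#' may then differ by more than one.
#'
#' @param peptides A [PeptideSet-class] or character vector of peptide
#'   ids.
#' @param n_pools Number of pools, `1 <= n_pools <=` number of peptides.
#' @param ordering_seed Integer seed for the shuffle.
#' @param group_by Optional named character vector mapping peptide id to
#'   a group key (`NULL`, the default, pools peptides independently).
#' @return `data.frame` with columns `pool_id, peptide_id`; pool ids are
#'   `Pool_1 ... Pool_<n_pools>`.
#' @export
#' @examples
#' pools <- assignPools(sprintf("pep%02d", 1:81), 16, ordering_seed = 7)
#' table(pools$pool_id)
assignPools <- function(peptides, n_pools, ordering_seed,
                        group_by = NULL) {
  ids <- if (is(peptides, "PeptideSet")) peptideIds(peptides)
         else as.character(peptides)
  n <- length(ids)
  n_pools <- as.integer(n_pools)
  if (is.na(n_pools) || n_pools < 1L)
    stop("n_pools must be a positive integer")
  if (n_pools > n)
    stop("n_pools (", n_pools, ") exceeds the number of peptides (", n, ")")
  if (anyDuplicated(ids)) stop("peptide ids must be unique")
  pool_names <- sprintf("Pool_%d", seq_len(n_pools))
  if (is.null(group_by)) {
    perm <- withSeed(ordering_seed, sample.int(n))
    shuffled <- ids[perm]
    pool <- pool_names[((seq_len(n) - 1L) %% n_pools) + 1L]
  } else {
    if (!all(ids %in% names(group_by)))
      stop("group_by must name every peptide id")
    grp <- split(ids, group_by[ids])
    grp <- grp[withSeed(ordering_seed, sample.int(length(grp)))]
    sizes <- integer(n_pools)
    pool <- character(n)
    shuffled <- character(0)
    for (g in grp) {
      target <- which.min(sizes)
      sizes[target] <- sizes[target] + length(g)
      pool[length(shuffled) + seq_along(g)] <- pool_names[target]
      shuffled <- c(shuffled, g)
    }
  }
  out <- data.frame(pool_id = pool, peptide_id = shuffled,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$pool_id, pool_names)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sizes of assigned pools
#'
#' @param pools Pool manifest from [assignPools()].
#' @return Named integer vector of member counts per pool.
#' @export
poolSizes <- function(pools) {
  stopifnot(is.data.frame(pools),
            all(c("pool_id", "peptide_id") %in% names(pools)))
  tab <- table(pools$pool_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(match(names(out), unique(pools$pool_id)))]
}

#' Deconvolute positive pools to a singleton retest list
#'
#' Pools that produced strong IFN-gamma responses are deconvoluted by
#' retesting their member peptides singly; this returns that retest
#' list: the union of members of the positive pools, deduplicated, in
#' pool order.
#'
#' @param pools Pool manifest from [assignPools()].
#' @param positive_pool_ids Character vector (or set) of positive pool
#'   ids; must all exist in `pools`.
#' @return Character vector of peptide ids to retest singly.
#' @export
#' @examples
#' pools <- data.frame(pool_id = c("P1", "P1", "P2"),
#'                     peptide_id = c("a", "b", "c"))
#' candidatesFromPositivePools(pools, "P1")
candidatesFromPositivePools <- function(pools, positive_pool_ids) {
  stopifnot(is.data.frame(pools),
            all(c("pool_id", "peptide_id") %in% names(pools)))
  positive_pool_ids <- as.character(positive_pool_ids)
  unknown <- setdiff(positive_pool_ids, pools$pool_id)
  if (length(unknown))
    stop("unknown pool id(s): ", paste(unknown, collapse = ", "))
  keep <- pools$pool_id %in% positive_pool_ids
  unique(pools$peptide_id[keep])
}

#' Classify the T cell subset recognizing a mutation
#'
#' Rolls per-peptide positivity in the sorted CD4 and CD8 ELISPOT arms
#' up to a subset label for one mutation: `dual` when both arms have at
#' least one positive peptide, `CD4_only`/`CD8_only` when exactly one
#' does, `none` otherwise.
#'
#' @param mutation_id Mutation identifier.
#' @param cd4_calls,cd8_calls Named logical vectors of per-peptide
#'   positivity in each arm (names are peptide ids; either may be
#'   empty, but not both).
#' @return List with `mutation_id`, `label` (one of `CD4_only`,
#'   `CD8_only`, `dual`, `none`), and the supporting positive peptide
#'   ids per arm (`cd4_positive`, `cd8_positive`).
#' @export
#' @examples
#' classifyEpitopeSubsets("Mut_48",
#'   cd4_calls = c(Mut_48.a6 = TRUE, Mut_48.a15 = FALSE),
#'   cd8_calls = c(Mut_48.a6 = TRUE))$label  # "dual"
classifyEpitopeSubsets <- function(mutation_id, cd4_calls = logical(0),
                                   cd8_calls = logical(0)) {
  if (!length(cd4_calls) && !length(cd8_calls))
    stop("nothing screened for mutation ", mutation_id,
         ": both arm call sets are empty")
  stopifnot(is.logical(cd4_calls), is.logical(cd8_calls))
  cd4_pos <- names(cd4_calls)[cd4_calls %in% TRUE]
  cd8_pos <- names(cd8_calls)[cd8_calls %in% TRUE]
  label <- if (length(cd4_pos) && length(cd8_pos)) "dual"
           else if (length(cd4_pos)) "CD4_only"
           else if (length(cd8_pos)) "CD8_only"
           else "none"
  list(mutation_id = as.character(mutation_id), label = label,
       cd4_positive = cd4_pos, cd8_positive = cd8_pos)
}

#' Roll single-peptide calls up to a mutation-level hit table
#'
#' One row per mutation with at least one positive single-peptide call,
#' giving the gene symbol, the T cell subset label (from the CD4/CD8
#' arm calls via [classifyEpitopeSubsets()]), and every contributing
#' positive peptide — so sibling peptides carrying the same mutation in
#' different products or at different anchors are listed together, as
#' an internal concordance control.
#'
#' @param calls `data.frame` of single-peptide calls with columns
#'   `stimulus_id` (peptide id), `arm` (`"CD4"` or `"CD8"`), and
#'   `positive` (logical), e.g. from [callPlate()].
#' @param manifest Peptide manifest (`data.frame` with `peptide_id`,
#'   `mutation_id`, `gene_symbol`) or a [PeptideSet-class].
#' @return `data.frame` with columns `mutation_id, gene, subset_label,
#'   positive_peptides` (comma-separated), ordered by mutation id;
#'   zero rows when nothing is positive.
#' @export
summarizeHits <- function(calls, manifest) {
  if (is(manifest, "PeptideSet")) manifest <- peptideManifest(manifest)
  stopifnot(is.data.frame(calls),
            all(c("stimulus_id", "arm", "positive") %in% names(calls)),
            all(c("peptide_id", "mutation_id") %in% names(manifest)))
  orphan <- setdiff(calls$stimulus_id, manifest$peptide_id)
  if (length(orphan))
    stop("called peptide(s) absent from the manifest: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  if (!all(calls$arm %in% c("CD4", "CD8")))
    stop("arm must be 'CD4' or 'CD8' for subset rollup")
  midx <- match(calls$stimulus_id, manifest$peptide_id)
  calls$mutation_id <- manifest$mutation_id[midx]
  empty <- data.frame(mutation_id = character(0), gene = character(0),
                      subset_label = character(0),
                      positive_peptides = character(0),
                      stringsAsFactors = FALSE)
  hit_mut <- sort(unique(calls$mutation_id[calls$positive %in% TRUE]))
  if (!length(hit_mut)) return(empty)
  rows <- lapply(hit_mut, function(m) {
    sub <- calls[calls$mutation_id == m, , drop = FALSE]
    armVec <- function(a) {
      s <- sub[sub$arm == a, , drop = FALSE]
      v <- s$positive %in% TRUE
      names(v) <- s$stimulus_id
      v
    }
    cls <- classifyEpitopeSubsets(m, armVec("CD4"), armVec("CD8"))
    gene <- manifest$gene_symbol[match(m, manifest$mutation_id)]
    pos <- sort(unique(c(cls$cd4_positive, cls$cd8_positive)))
    data.frame(mutation_id = m,
               gene = if (is.null(gene)) NA_character_ else gene,
               subset_label = cls$label,
               positive_peptides = paste(pos, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write pool manifests and hit tables
#'
#' Tab-delimited: pool manifests have columns `pool_id, peptide_id`;
#' hit tables have `mutation_id, gene, subset_label, positive_peptides`.
#'
#' @param x Object to write.
#' @param file Path.
#' @return Readers return a `data.frame`; writers return `file`
#'   invisibly.
#' @export
writePoolManifest <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePoolManifest
#' @export
readPoolManifest <- function(file) read.delim(file, stringsAsFactors = FALSE)

#' @rdname writePoolManifest
#' @export
writeHitTable <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePoolManifest
#' @export
readHitTable <- function(file) read.delim(file, stringsAsFactors = FALSE)
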