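#' Simulation configuration for synthetic screening fixtures
#'
#' Bundles and validates every knob of the synthetic-data generators.
#' Defaults emulate the screening conditions the pipeline is built for:
#' a variant cascade of 4771 total / 1481 coding / 270 expressed / 39
#' strict variants, background ELISPOT wells at 10 SFC, immunogenic
#' wells at 15x background, 3 replicate wells, 16 peptide pools, and 4
#' immunogenic mutations of which 1 is recognized by both T cell
#' subsets (the rest CD4-only).
#'
#' @param seed Integer master seed; every generator derives its own
#'   stream from it (fixed per-generator offsets, see the vignette), so
#'   identical configs give byte-identical outputs.
#' @param tier_counts Integer vector `(n_total, n_coding, n_expressed,
#'   n_strict)`, non-increasing.
#' @param rna_depth_range Integer interval for simulated tumor-RNA
#'   depths; the upper end must be at least 50 when a strict tier is
#'   requested so strict VAF/read thresholds are satisfiable.
#' @param n_proteins,protein_length_range Size and length range of the
#'   toy proteome.
#' @param lambda_background Positive Poisson rate of control/background
#'   wells (SFC per well).
#' @param effect_multiplier Rate multiplier (`>= 1`) applied to wells
#'   stimulated with a planted immunogenic peptide (or a pool holding
#'   one).
#' @param n_replicates Replicate wells per condition (`>= 2`).
#' @param n_immunogenic Number of strict-tier mutations planted as
#'   immunogenic.
#' @param n_dual,n_cd8_only Of the immunogenic mutations, how many are
#'   recognized by both subsets / by CD8 only; the remainder are
#'   CD4-only.
#' @param n_pools Pools for the first-stage screen.
#' @param anchors,peptide_length Long-peptide design parameters.
#' @param overdispersion `NULL` for Poisson wells (default) or a
#'   positive negative-binomial `size` for overdispersed wells.
#' @return A validated list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1, tier_counts = c(100, 60, 30, 10))
#' cfg$tier_counts
simulationConfig <- function(seed = 1L,
                             tier_counts = c(4771L, 1481L, 270L, 39L),
                             rna_depth_range = c(30L, 200L),
                             n_proteins = 40L,
                             protein_length_range = c(80L, 400L),
                             lambda_background = 10,
                             effect_multiplier = 15,
                             n_replicates = 3L,
                             n_immunogenic = 4L,
                             n_dual = 1L,
                             n_cd8_only = 0L,
                             n_pools = 16L,
                             anchors = c(6L, 15L),
                             peptide_length = 20L,
                             overdispersion = NULL) {
  tier_counts <- as.integer(tier_counts)
  if (length(tier_counts) != 4L || anyNA(tier_counts) ||
      any(tier_counts < 0L))
    stop("tier_counts must be four non-negative integers")
  if (is.unsorted(rev(tier_counts)))
    stop("tier_counts must be non-increasing: ",
         "total >= coding >= expressed >= strict")
  rna_depth_range <- as.integer(rna_depth_range)
  if (length(rna_depth_range) != 2L || anyNA(rna_depth_range) ||
      rna_depth_range[1L] < 1L ||
      rna_depth_range[1L] > rna_depth_range[2L])
    stop("rna_depth_range must be a positive integer interval")
  if (tier_counts[4L] > 0L && rna_depth_range[2L] < 50L)
    stop("rna_depth_range[2] must be >= 50 to make the strict tier ",
         "(VAF >= 0.20 and >= 10 variant reads) satisfiable")
  protein_length_range <- as.integer(protein_length_range)
  if (length(protein_length_range) != 2L || anyNA(protein_length_range) ||
      protein_length_range[1L] < 1L ||
      protein_length_range[1L] > protein_length_range[2L])
    stop("degenerate protein_length_range")
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (!is.numeric(lambda_background) || lambda_background <= 0)
    stop("lambda_background must be positive")
  if (!is.numeric(effect_multiplier) || effect_multiplier < 1)
    stop("effect_multiplier must be >= 1")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  n_immunogenic <- as.integer(n_immunogenic)
  n_dual <- as.integer(n_dual); n_cd8_only <- as.integer(n_cd8_only)
  if (n_immunogenic < 0L || n_immunogenic > tier_counts[4L])
    stop("n_immunogenic must lie in [0, n_strict]")
  if (n_dual < 0L || n_cd8_only < 0L ||
      n_dual + n_cd8_only > n_immunogenic)
    stop("n_dual + n_cd8_only must not exceed n_immunogenic")
  if (n_pools < 1L) stop("n_pools must be >= 1")
  if (!is.null(overdispersion) &&
      (!is.numeric(overdispersion) || overdispersion <= 0))
    stop("overdispersion must be NULL or a positive size parameter")
  structure(list(seed = as.integer(seed), tier_counts = tier_counts,
                 rna_depth_range = rna_depth_range,
                 n_proteins = as.integer(n_proteins),
                 protein_length_range = protein_length_range,
                 lambda_background = lambda_background,
                 effect_multiplier = effect_multiplier,
                 n_replicates = as.integer(n_replicates),
                 n_immunogenic = n_immunogenic, n_dual = n_dual,
                 n_cd8_only = n_cd8_only, n_pools = as.integer(n_pools),
                 anchors = as.integer(anchors),
                 peptide_length = as.integer(peptide_length),
                 overdispersion = overdispersion),
            class = "simulation_config")
}

# fixed stream offsets per generator
.STREAMS <- c(proteome = 1L, variants = 2L, plate_pool = 3L,
              plate_single_bulk = 4L, plate_cd4 = 5L, plate_cd8 = 6L,
              immunogenic = 7L, pooling = 8L)

#' Generate a toy proteome
#'
#' Random protein sequences uniform over the 20 canonical residues,
#' with lengths drawn from the configured range. Deterministic given
#' the config seed.
#'
#' @param config A [simulationConfig()].
#' @return Named `AAStringSet` (`Prot_1 ...`) with `gene_symbol` and
#'   `isoform_label` metadata columns.
#' @export
genProteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withSeed(deriveSeed(config$seed, .STREAMS[["proteome"]]), {
    lens <- sample(seq(config$protein_length_range[1L],
                       config$protein_length_range[2L]),
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1L))
    out <- AAStringSet(seqs)
    names(out) <- sprintf("Prot_%d", seq_len(config$n_proteins))
    mcols(out) <- DataFrame(
      gene_symbol = sprintf("Gene%d", seq_len(config$n_proteins)),
      isoform_label = "iso1")
    out
  })
}

#' Generate a variant table with planted cascade tiers
#'
#' Emits exactly `tier_counts[i]` variants surviving each tier of the
#' expression-filter cascade under the default thresholds: noncoding
#' variants fill `total - coding`; coding-but-unexpressed variants have
#' zero variant RNA reads; expressed-but-not-strict variants have at
#' least one variant read but fail the strict thresholds (too few reads
#' or VAF below 20%); strict-tier variants satisfy VAF >= 0.20 and >=
#' 10 variant reads by construction and are all missense, so every
#' strict variant is design-eligible. Row order is shuffled so tier
#' membership cannot be read off position.
#'
#' @param config A [simulationConfig()].
#' @param proteome Proteome from [genProteome()] (source of transcript
#'   ids, positions, and reference residues for coding variants).
#' @return List with `variants` (canonical variant `data.frame`) and
#'   `truth` (`data.frame` of `variant_id`, deepest `tier` reached:
#'   `noncoding`, `coding`, `expressed`, or `strict`).
#' @export
genVariantTable <- function(config, proteome) {
  stopifnot(inherits(config, "simulation_config"),
            is(proteome, "AAStringSet"), length(proteome) >= 1L)
  tc <- config$tier_counts
  n_total <- tc[1L]; n_coding <- tc[2L]
  n_expressed <- tc[3L]; n_strict <- tc[4L]
  n_noncoding <- n_total - n_coding
  n_unexpressed <- n_coding - n_expressed
  n_exp_only <- n_expressed - n_strict
  lo <- config$rna_depth_range[1L]; hi <- config$rna_depth_range[2L]
  prot_seq <- as.character(proteome)
  prot_len <- nchar(prot_seq)

  withSeed(deriveSeed(config$seed, .STREAMS[["variants"]]), {
    tier <- rep(c("strict", "expressed", "coding", "noncoding"),
                times = c(n_strict, n_exp_only, n_unexpressed,
                          n_noncoding))
    n <- length(tier)
    coding <- tier != "noncoding"
    nc <- sum(coding)

    # protein context for coding variants
    pidx <- sample.int(length(proteome), nc, replace = TRUE)
    ppos <- floor(runif(nc) * prot_len[pidx]) + 1L
    aa_ref <- substring(prot_seq[pidx], ppos, ppos)
    # shift within the alphabet guarantees aa_alt != aa_ref
    shift <- sample.int(19L, nc, replace = TRUE)
    aa_alt <- AA_ALPHABET[(match(aa_ref, AA_ALPHABET) + shift - 1L) %%
                            20L + 1L]
    # strict-tier variants are all missense; other coding tiers mix in
    # synonymous variants (no amino-acid change recorded)
    cls_coding <- rep("missense", nc)
    tier_coding <- tier[coding]
    nonstrict <- which(tier_coding != "strict")
    if (length(nonstrict))
      cls_coding[nonstrict[seq_along(nonstrict) %% 3L == 0L]] <-
        "synonymous"
    aa_ref[cls_coding == "synonymous"] <- NA_character_
    aa_alt[cls_coding == "synonymous"] <- NA_character_

    class <- rep("noncoding", n)
    class[coding] <- cls_coding
    protein_pos <- rep(NA_integer_, n)
    protein_pos[coding] <- ppos
    gene <- rep(NA_character_, n)
    gene[coding] <- mcols(proteome)$gene_symbol[pidx]
    transcript <- rep(NA_character_, n)
    transcript[coding] <- names(proteome)[pidx]

    # RNA evidence per tier
    rna_depth <- integer(n); rna_alt <- integer(n)
    is_strict <- tier == "strict"
    if (n_strict) {
      d <- sample(50:max(hi, 60L), n_strict, replace = TRUE)
      min_alt <- pmax(10L, as.integer(ceiling(0.2 * d)))
      a <- pmax(min_alt, rbinom(n_strict, d, 0.4))
      rna_depth[is_strict] <- d; rna_alt[is_strict] <- a
    }
    is_exp <- tier == "expressed"
    if (n_exp_only) {
      # alternate the two failure modes where depth permits: too few
      # variant reads (alt < 10) vs VAF below 20% with alt >= 10
      d <- sample(lo:hi, n_exp_only, replace = TRUE)
      a <- integer(n_exp_only)
      low_vaf_ok <- d >= 55L & seq_len(n_exp_only) %% 2L == 0L
      a[!low_vaf_ok] <- 1L + as.integer(
        floor(runif(sum(!low_vaf_ok)) * pmin(9L, d[!low_vaf_ok])))
      if (any(low_vaf_ok)) {
        dmax <- as.integer(floor(0.19 * d[low_vaf_ok]))
        a[low_vaf_ok] <- 10L + as.integer(
          floor(runif(sum(low_vaf_ok)) * (dmax - 9L)))
      }
      rna_depth[is_exp] <- d; rna_alt[is_exp] <- a
    }
    is_unexp <- tier == "coding"
    if (n_unexpressed) {
      rna_depth[is_unexp] <- sample(0:hi, n_unexpressed, replace = TRUE)
      rna_alt[is_unexp] <- 0L
    }
    is_nonc <- tier == "noncoding"
    if (n_noncoding) {
      d <- sample(0:hi, n_noncoding, replace = TRUE)
      rna_depth[is_nonc] <- d
      rna_alt[is_nonc] <- rbinom(n_noncoding, d, 0.1)
    }

    dna_depth <- sample(60:150, n, replace = TRUE)
    dna_alt <- pmax(1L, rbinom(n, dna_depth, 0.35))

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) + sample.int(3L, n, replace = TRUE)
                  - 1L) %% 4L + 1L]

    ord <- sample.int(n)
    df <- data.frame(
      variant_id = sprintf("V%04d", seq_len(n)),
      chrom = sample(paste0("chr", 1:19), n, replace = TRUE)[ord],
      pos = sample.int(1e8L, n, replace = TRUE)[ord],
      ref = ref[ord], alt = alt[ord], class = class[ord],
      gene = gene[ord], transcript = transcript[ord],
      protein_pos = protein_pos[ord], aa_ref = aa_ref_full(aa_ref,
        class, coding)[ord], aa_alt = aa_ref_full(aa_alt, class,
        coding)[ord],
      dna_alt = dna_alt[ord], dna_ref = (dna_depth - dna_alt)[ord],
      rna_alt = rna_alt[ord], rna_depth = rna_depth[ord],
      stringsAsFactors = FALSE)
    truth <- data.frame(variant_id = df$variant_id, tier = tier[ord],
                        stringsAsFactors = FALSE)
    validateVariantTable(df)
    list(variants = df, truth = truth)
  })
}

# expand per-coding-variant amino-acid vectors to full length
aa_ref_full <- function(aa_coding, class, coding) {
  out <- rep(NA_character_, length(class))
  out[coding] <- aa_coding
  out
}

#' Generate an ELISPOT plate with planted immunogenic stimuli
#'
#' Control and non-immunogenic stimulus wells draw from
#' `Poisson(lambda_background)`; wells stimulated with a planted
#' immunogenic peptide (or a pool containing one) draw from
#' `Poisson(effect_multiplier * lambda_background)`. With
#' `overdispersion` set in the config, wells are negative binomial with
#' the same means. Deterministic given the config seed and `stream`.
#'
#' @param config A [simulationConfig()].
#' @param stimulus_ids Stimuli on the plate (peptide or pool ids).
#' @param immunogenic_ids Subset of `stimulus_ids` planted as
#'   immunogenic.
#' @param arm Condition arm label (`"bulk"`, `"CD4"`, or `"CD8"`).
#' @param control_id Id for the no-peptide control wells (default
#'   `"control"`).
#' @param stream Integer stream offset separating plates generated from
#'   one master seed.
#' @return Long-format plate `data.frame` with columns `stimulus_id,
#'   arm, tissue, well_index, sfc`.
#' @export
genElispotPlate <- function(config, stimulus_ids,
                            immunogenic_ids = character(0),
                            arm = "bulk", control_id = "control",
                            stream = .STREAMS[["plate_pool"]]) {
  stopifnot(inherits(config, "simulation_config"),
            length(stimulus_ids) >= 1L)
  extra <- setdiff(immunogenic_ids, stimulus_ids)
  if (length(extra))
    stop("immunogenic id(s) not on the plate: ",
         paste(extra, collapse = ", "))
  stim <- c(control_id, as.character(stimulus_ids))
  rate <- ifelse(stim %in% immunogenic_ids,
                 config$effect_multiplier * config$lambda_background,
                 config$lambda_background)
  nr <- config$n_replicates
  withSeed(deriveSeed(config$seed, stream), {
    mu <- rep(rate, each = nr)
    sfc <- if (is.null(config$overdispersion)) rpois(length(mu), mu)
           else rnbinom(length(mu), size = config$overdispersion,
                        mu = mu)
    data.frame(stimulus_id = rep(stim, each = nr), arm = arm,
               tissue = NA_character_,
               well_index = rep(seq_len(nr), times = length(stim)),
               sfc = sfc, stringsAsFactors = FALSE)
  })
}

#' Build a complete synthetic screening fixture
#'
#' Generates every input of the two-stage screen with planted truth:
#' toy proteome, variant table with planted cascade tiers, designed
#' mutant/wild-type peptides for the strict tier, pool assignment of
#' the mutant peptides, and four ELISPOT plates — the first-stage
#' pooled bulk screen, the second-stage singleton bulk screen (all
#' mutant peptides, so deconvolution can subset it), and the sorted
#' CD4/CD8 arm plates for subset attribution. `n_immunogenic` strict
#' mutations are planted as immunogenic with the configured subset
#' labels; all mutant peptides of an immunogenic mutation are hot in
#' the bulk plates and in the arms their label implies.
#'
#' @param config A [simulationConfig()].
#' @return List of class `neoscreen_fixture` with elements `config`,
#'   `proteome`, `variants`, `peptides` ([PeptideSet-class], mutant and
#'   wild-type), `pools` (mutant peptides only), `plates` (named list
#'   `pool_bulk`, `single_bulk`, `single_cd4`, `single_cd8`), and
#'   `truth` (list: `tiers`, `immunogenic` with per-mutation labels,
#'   `hot_peptides` per arm, and the expected `hits` table).
#' @seealso [runScreen()], [writeFixture()]
#' @export
endToEndFixture <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  proteome <- genProteome(config)
  gv <- genVariantTable(config, proteome)
  strict <- filterStrict(filterRnaExpressed(filterCoding(gv$variants)))
  peptides <- designFromVariants(strict, proteome,
                                 anchors = config$anchors,
                                 length = config$peptide_length)
  mut_pep <- peptides[isMutant(peptides)]
  if (config$n_pools > length(mut_pep))
    stop("n_pools exceeds the number of designed mutant peptides")

  imm_mut <- withSeed(deriveSeed(config$seed, .STREAMS[["immunogenic"]]),
                      sample(strict$variant_id, config$n_immunogenic))
  labels <- rep("CD4_only", config$n_immunogenic)
  if (config$n_dual) labels[seq_len(config$n_dual)] <- "dual"
  if (config$n_cd8_only)
    labels[config$n_dual + seq_len(config$n_cd8_only)] <- "CD8_only"
  immunogenic <- data.frame(mutation_id = imm_mut, label = labels,
                            stringsAsFactors = FALSE)

  man <- peptideManifest(mut_pep)
  hotFor <- function(labs)
    man$peptide_id[man$mutation_id %in%
                     immunogenic$mutation_id[immunogenic$label %in% labs]]
  hot <- list(bulk = hotFor(c("CD4_only", "CD8_only", "dual")),
              CD4 = hotFor(c("CD4_only", "dual")),
              CD8 = hotFor(c("CD8_only", "dual")))

  pools <- assignPools(mut_pep, config$n_pools,
                       ordering_seed = deriveSeed(config$seed,
                                                  .STREAMS[["pooling"]]))
  hot_pools <- unique(pools$pool_id[pools$peptide_id %in% hot$bulk])

  plates <- list(
    pool_bulk = genElispotPlate(config, unique(pools$pool_id),
                                hot_pools, arm = "bulk",
                                stream = .STREAMS[["plate_pool"]]),
    single_bulk = genElispotPlate(config, man$peptide_id, hot$bulk,
                                  arm = "bulk",
                                  stream = .STREAMS[["plate_single_bulk"]]),
    single_cd4 = genElispotPlate(config, man$peptide_id, hot$CD4,
                                 arm = "CD4",
                                 stream = .STREAMS[["plate_cd4"]]),
    single_cd8 = genElispotPlate(config, man$peptide_id, hot$CD8,
                                 arm = "CD8",
                                 stream = .STREAMS[["plate_cd8"]]))

  hits <- do.call(rbind, lapply(seq_len(nrow(immunogenic)), function(i) {
    m <- immunogenic$mutation_id[i]
    data.frame(mutation_id = m,
               gene = man$gene_symbol[match(m, man$mutation_id)],
               subset_label = immunogenic$label[i],
               positive_peptides = paste(
                 sort(man$peptide_id[man$mutation_id == m]),
                 collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(mutation_id = character(0), gene = character(0),
                       subset_label = character(0),
                       positive_peptides = character(0))
  else hits <- hits[order(hits$mutation_id), , drop = FALSE]
  rownames(hits) <- NULL

  structure(list(config = config, proteome = proteome,
                 variants = gv$variants, peptides = peptides,
                 pools = pools, plates = plates,
                 truth = list(tiers = gv$truth,
                              immunogenic = immunogenic,
                              hot_peptides = hot, hot_pools = hot_pools,
                              hits = hits)),
            class = "neoscreen_fixture")
}

#' Run the two-stage screen on a synthetic fixture
#'
#' Executes the full pipeline downstream of peptide design: call the
#' pooled bulk plate, deconvolute positive pools into a singleton
#' retest list, call the retested peptides on the singleton bulk plate,
#' then call the bulk-positive peptides in the sorted CD4/CD8 arm
#' plates and roll the arm calls up to a mutation-level hit table with
#' subset labels.
#'
#' @param fixture A fixture from [endToEndFixture()].
#' @param ... Criterion thresholds passed to [callPlate()].
#' @return List with `pool_calls`, `retest_ids`, `single_calls` (bulk),
#'   `arm_calls` (CD4 + CD8), and `hits` (see [summarizeHits()]).
#' @export
runScreen <- function(fixture, ...) {
  stopifnot(inherits(fixture, "neoscreen_fixture"))
  pool_calls <- callPlate(fixture$plates$pool_bulk, ...)
  pos_pools <- pool_calls$stimulus_id[pool_calls$positive]
  retest <- candidatesFromPositivePools(fixture$pools, pos_pools)

  subsetPlate <- function(plate, ids)
    plate[plate$stimulus_id %in% c("control", ids), , drop = FALSE]
  single_calls <- callPlate(subsetPlate(fixture$plates$single_bulk,
                                        retest), ...)
  bulk_pos <- single_calls$stimulus_id[single_calls$positive]

  arm_calls <- rbind(
    callPlate(subsetPlate(fixture$plates$single_cd4, bulk_pos), ...),
    callPlate(subsetPlate(fixture$plates$single_cd8, bulk_pos), ...))
  hits <- summarizeHits(arm_calls, fixture$peptides)
  list(pool_calls = pool_calls, retest_ids = retest,
       single_calls = single_calls, arm_calls = arm_calls, hits = hits)
}

#' Compare a recovered hit table with planted truth
#'
#' @param hits Hit table from [runScreen()]/[summarizeHits()].
#' @param truth_hits Expected hit table (e.g. `fixture$truth$hits`).
#' @return `TRUE` iff both tables name the same mutations with the same
#'   subset labels and the same positive peptide sets.
#' @export
hitsMatchTruth <- function(hits, truth_hits) {
  if (!setequal(hits$mutation_id, truth_hits$mutation_id)) return(FALSE)
  idx <- match(hits$mutation_id, truth_hits$mutation_id)
  if (!all(hits$subset_label == truth_hits$subset_label[idx]))
    return(FALSE)
  peps <- strsplit(hits$positive_peptides, ",", fixed = TRUE)
  tpeps <- strsplit(truth_hits$positive_peptides[idx], ",", fixed = TRUE)
  all(mapply(setequal, peps, tpeps))
}

#' Write a fixture bundle to disk
#'
#' Emits every file format the pipeline consumes: proteome FASTA,
#' canonical variant table, peptide FASTA + manifest, pool manifest,
#' the four plate tables, and a `truth.json` sidecar.
#'
#' @param fixture A fixture from [endToEndFixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "neoscreen_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeXStringSet(fixture$proteome, p("proteome.fasta"))
  writeVariantTable(fixture$variants, p("variants.tsv"))
  writePeptideFasta(fixture$peptides, p("peptides.fasta"))
  writePeptideManifest(fixture$peptides, p("peptides.tsv"))
  writePoolManifest(fixture$pools, p("pools.tsv"))
  for (nm in names(fixture$plates))
    writePlate(fixture$plates[[nm]], p(sprintf("plate_%s.tsv", nm)))
  truth <- fixture$truth
  jsonlite::write_json(
    list(tiers = truth$tiers, immunogenic = truth$immunogenic,
         hot_peptides = truth$hot_peptides,
         hot_pools = truth$hot_pools, hits = truth$hits),
    p("truth.json"), dataframe = "columns", auto_unbox = TRUE)
  invisible(dir)
}
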