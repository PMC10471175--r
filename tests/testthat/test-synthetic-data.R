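test_that("config validation rejects impossible study conditions", {
  expect_error(simulationConfig(tier_counts = c(10, 20, 5, 1)),
               "non-increasing")
  expect_error(simulationConfig(tier_counts = c(10, 8, 5, -1)),
               "non-negative")
  expect_error(simulationConfig(effect_multiplier = 0.5), ">= 1")
  expect_error(simulationConfig(n_replicates = 1), ">= 2")
  expect_error(simulationConfig(n_immunogenic = 99,
                                tier_counts = c(50, 30, 20, 5)),
               "n_immunogenic")
  expect_error(simulationConfig(protein_length_range = c(50, 10)),
               "degenerate")
  expect_error(simulationConfig(rna_depth_range = c(5, 20)), ">= 50")
  expect_error(simulationConfig(lambda_background = 0), "positive")
})

test_that("proteome generation is deterministic and alphabet-bounded", {
  cfg <- smallConfig(seed = 9)
  p1 <- genProteome(cfg)
  p2 <- genProteome(cfg)
  expect_identical(as.character(p1), as.character(p2))
  expect_length(p1, cfg$n_proteins)
  w <- Biostrings::width(p1)
  expect_true(all(w >= cfg$protein_length_range[1] &
                    w <= cfg$protein_length_range[2]))
  residues <- unique(strsplit(paste(as.character(p1), collapse = ""),
                              "")[[1]])
  expect_true(all(residues %in% neoscreen:::AA_ALPHABET))
  # byte-identical FASTA on re-generation
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(p1, f1)
  Biostrings::writeXStringSet(genProteome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("variant generator plants exact cascade tiers", {
  cfg <- smallConfig(seed = 2)
  prot <- genProteome(cfg)
  gv <- genVariantTable(cfg, prot)
  expect_equal(unname(tierCounts(cascadeSummary(gv$variants))),
               c(100L, 60L, 30L, 10L))
  # regeneration is byte-identical
  gv2 <- genVariantTable(cfg, prot)
  expect_identical(gv$variants, gv2$variants)
  # model constraint: rna_alt <= rna_depth everywhere
  expect_true(all(gv$variants$rna_alt <= gv$variants$rna_depth))
  expect_silent(validateVariantTable(gv$variants))
  # strict-tier truth re-checked by an independent threshold oracle
  strict_ids <- gv$truth$variant_id[gv$truth$tier == "strict"]
  sv <- gv$variants[gv$variants$variant_id %in% strict_ids, ]
  expect_true(all(sv$rna_alt >= 10 &
                    sv$rna_alt / sv$rna_depth >= 0.2))
  expect_true(all(sv$class == "missense"))
  # truth tiers agree with the filters variant by variant
  expressed_ids <- gv$truth$variant_id[gv$truth$tier %in%
                                         c("expressed", "strict")]
  expect_setequal(
    filterRnaExpressed(filterCoding(gv$variants))$variant_id,
    expressed_ids)
})

test_that("planted tiers are recovered over a grid of configs", {
  grid <- expand.grid(total = c(30L, 80L), coding = c(20L, 10L),
                      expressed = c(8L, 5L), strict = c(4L, 0L))
  for (i in seq_len(nrow(grid))) {
    tiers <- unlist(grid[i, ], use.names = FALSE)
    cfg <- smallConfig(seed = 100 + i, tiers = tiers)
    vt <- genVariantTable(cfg, genProteome(cfg))$variants
    expect_equal(unname(tierCounts(cascadeSummary(vt))), tiers)
  }
})

test_that("plate generator plants immunogenic rates deterministically", {
  cfg <- smallConfig(seed = 4)
  stim <- sprintf("pep%d", 1:40)
  plate <- genElispotPlate(cfg, stim, immunogenic_ids = "pep3")
  expect_identical(plate, genElispotPlate(cfg, stim,
                                          immunogenic_ids = "pep3"))
  expect_equal(nrow(plate), (40 + 1) * cfg$n_replicates)
  hot <- plate$sfc[plate$stimulus_id == "pep3"]
  # Poisson mean 150 across 3 wells: within 3 standard errors
  expect_lt(abs(mean(hot) - 150), 3 * sqrt(150 / 3))
  cold <- plate$sfc[plate$stimulus_id != "pep3"]
  expect_lt(mean(cold), 20)
  expect_error(genElispotPlate(cfg, stim, immunogenic_ids = "ghost"),
               "not on the plate")
  # null case: multiplier 1 leaves planted wells at background
  cfg1 <- smallConfig(seed = 4, effect_multiplier = 1)
  null_plate <- genElispotPlate(cfg1, stim, immunogenic_ids = "pep3")
  expect_lt(mean(null_plate$sfc), 15)
  # overdispersed wells keep the planted mean
  cfgo <- smallConfig(seed = 4, overdispersion = 5)
  od <- genElispotPlate(cfgo, stim, immunogenic_ids = "pep3")
  expect_lt(abs(mean(od$sfc[od$stimulus_id == "pep3"]) - 150),
            5 * sqrt(150 + 150^2 / 5) / sqrt(3))
})

test_that("the full screen recovers planted truth on a strong fixture", {
  fx <- endToEndFixture(simulationConfig(
    seed = 42, tier_counts = c(120L, 90L, 60L, 20L), n_proteins = 12L,
    n_immunogenic = 4L, n_dual = 1L, n_pools = 8L))
  # fixture bookkeeping is internally consistent
  expect_equal(sum(isMutant(fx$peptides)) + sum(!isMutant(fx$peptides)),
               length(fx$peptides))
  expect_setequal(fx$pools$peptide_id,
                  peptideIds(fx$peptides)[isMutant(fx$peptides)])
  res <- runScreen(fx)
  expect_true(all(fx$truth$hot_pools %in%
                    res$pool_calls$stimulus_id[res$pool_calls$positive]))
  expect_true(all(fx$truth$hot_peptides$bulk %in% res$retest_ids))
  expect_true(hitsMatchTruth(res$hits, fx$truth$hits))
  expect_setequal(res$hits$subset_label, c("dual", "CD4_only"))
  # determinism of the whole bundle
  fx2 <- endToEndFixture(simulationConfig(
    seed = 42, tier_counts = c(120L, 90L, 60L, 20L), n_proteins = 12L,
    n_immunogenic = 4L, n_dual = 1L, n_pools = 8L))
  expect_identical(fx$variants, fx2$variants)
  expect_identical(fx$plates, fx2$plates)
})

test_that("a null screen (multiplier 1) yields zero hits", {
  for (s in 1:3) {
    fx <- endToEndFixture(simulationConfig(
      seed = s, tier_counts = c(60L, 40L, 25L, 12L), n_proteins = 10L,
      effect_multiplier = 1, n_immunogenic = 3L, n_dual = 1L,
      n_pools = 6L))
    res <- runScreen(fx)
    expect_equal(nrow(res$hits), 0L)
  }
})

test_that("fixture bundles write every pipeline file format", {
  dir <- withr::local_tempdir()
  fx <- endToEndFixture(simulationConfig(
    seed = 5, tier_counts = c(40L, 30L, 20L, 8L), n_proteins = 8L,
    n_immunogenic = 2L, n_dual = 1L, n_pools = 4L))
  writeFixture(fx, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "proteome.fasta", "variants.tsv", "peptides.fasta", "peptides.tsv",
    "pools.tsv", "plate_pool_bulk.tsv", "plate_single_bulk.tsv",
    "plate_single_cd4.tsv", "plate_single_cd8.tsv", "truth.json")))))
  # written table re-enters the pipeline unchanged
  vt <- readVariantTable(file.path(dir, "variants.tsv"))
  expect_equal(unname(tierCounts(cascadeSummary(vt))),
               c(40L, 30L, 20L, 8L))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$hits$mutation_id, fx$truth$hits$mutation_id)
})
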