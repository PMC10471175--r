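# Shared fixture builders. Everything is generated in code at test time.

randomProtein <- function(len) {
  paste(sample(neoscreen:::AA_ALPHABET, len, replace = TRUE),
        collapse = "")
}

# Minimal hand-built variant table covering every tier; columns follow
# the canonical layout.
toyVariants <- function() {
  data.frame(
    variant_id = sprintf("v%02d", 1:6),
    chrom = "chr1", pos = 1:6 * 100L,
    ref = "A", alt = "T",
    class = c("noncoding", "synonymous", "missense", "missense",
              "missense", "missense"),
    gene = c(NA, "G2", "G3", "G4", "G5", "G6"),
    transcript = c(NA, "T2", "T3", "T4", "T5", "T6"),
    protein_pos = c(NA, 10L, 10L, 10L, 10L, 10L),
    aa_ref = c(NA, NA, "A", "A", "A", "A"),
    aa_alt = c(NA, NA, "V", "V", "V", "V"),
    dna_alt = 30L, dna_ref = 70L,
    #            nonc  unexpr  expr-lowreads  expr-lowvaf  strict  strict
    rna_alt   = c(5L,  0L,     3L,            12L,         12L,    50L),
    rna_depth = c(50L, 40L,    30L,           120L,        48L,    100L),
    stringsAsFactors = FALSE)
}

# Independent one-pass recount of the cascade (brute-force oracle).
oracleCascade <- function(variants, min_alt = 1, min_vaf = 0.20,
                          min_reads = 10) {
  n_total <- nrow(variants)
  coding <- variants[variants$class != "noncoding", , drop = FALSE]
  expressed <- coding[coding$rna_alt >= min_alt, , drop = FALSE]
  ok <- expressed$rna_depth > 0 &
    expressed$rna_alt / pmax(expressed$rna_depth, 1) >= min_vaf &
    expressed$rna_alt >= min_reads
  c(n_total, nrow(coding), nrow(expressed), sum(ok))
}

smallConfig <- function(seed = 1, tiers = c(100L, 60L, 30L, 10L), ...) {
  n_imm <- min(4L, tiers[4L])
  simulationConfig(seed = seed, tier_counts = tiers, n_proteins = 8L,
                   protein_length_range = c(60L, 150L),
                   n_immunogenic = n_imm, n_dual = min(1L, n_imm), ...)
}
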