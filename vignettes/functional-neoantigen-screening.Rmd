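---
title: "Function-first neoantigen screening: models, parameters, and design choices"
author: "neoscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-first neoantigen screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

## The problem

Most neoantigen (NeoAg) discovery pipelines are prediction-first: somatic
mutations are ranked by predicted MHC binding affinity and only the top
binders are synthesized and tested. `neoscreen` implements the complementary
*function-first* strategy: every well-expressed coding mutation is carried
into peptide synthesis and screened for recognition by the endogenous T cell
repertoire, with binding predictions consumed only afterwards, as an audit.
The package covers the computational spine of such a screen:

1. **Variant cascade** — winnow annotated somatic variants by coding
   consequence, RNA expression evidence, and strict expression thresholds.
2. **Peptide design** — turn each surviving missense mutation into a pair of
   20-mer peptides (mutant and wild-type) with the mutated residue placed at
   defined anchor positions, plus 10/15-mer tiles for minimal-epitope
   mapping and tethered helper–effector constructs.
3. **Pooled screening** — assign peptides to pools, call IFN-γ ELISPOT
   positivity with a four-criterion rule, deconvolute positive pools, and
   roll single-peptide calls up to mutation-level hits with CD4/CD8 subset
   attribution.
4. **Prediction audit** — quantify how efficiently a standard IC50 cutoff
   would have captured the functionally validated epitopes.
5. **Synthetic data** — generate all of the above with planted truth, so the
   pipeline is testable end to end without any sequencing data.

## The variant cascade

A variant table carries, per variant, its consequence class, tumor-DNA
allele counts, and tumor-RNA evidence: `rna_alt` (reads carrying the variant
base) and `rna_depth` (total reads at the site). Three nested filters define
the tiers:

* **coding**: consequence class in the coding set (default: everything
  except `noncoding`; synonymous variants stay in this tier, though only
  protein-altering variants proceed to design);
* **expressed**: `rna_alt >= 1` — a single read of the variant base counts
  as expression evidence;
* **strict**: RNA VAF `rna_alt / rna_depth >= 0.20` **and** `rna_alt >= 10`,
  both inclusive.

Two points are deliberately configurable because the underlying convention
varies between groups. First, the strict read threshold can be interpreted
against variant-supporting reads (`strict_reads_mode = "alt"`, the default,
consistent with the expression tier's "read of the variant base" logic) or
against total site depth (`"depth"`). Second, the VAF is computed from RNA
counts by default — the strict tier is an *expression* threshold — while DNA
counts are carried in the table for workflows that prefer a DNA VAF.
Variants with zero RNA depth have undefined VAF and simply fail the
expressed/strict tiers; they are never errors.

```{r cascade}
cfg <- simulationConfig(seed = 1, tier_counts = c(100, 60, 30, 10),
                        n_proteins = 8)
vt <- genVariantTable(cfg, genProteome(cfg))$variants
cascadeSummary(vt)
```

## Long-peptide design

For a missense mutation at protein residue $m$, a peptide of length $L$
(default 20) with the mutation at anchor $a$ spans residues
$[m-a+1,\; m-a+L]$. The defaults $a \in \{6, 15\}$ yield two peptides per
mutation whose mutated residue is asymmetrically placed, so that downstream
proteolytic processing can liberate both short (MHC I) and long (MHC II)
minimal epitopes containing the mutation. Each mutant peptide is emitted
with its wild-type counterpart over the same window — the WT pair is the
specificity control in screening.

Near a protein terminus a requested anchor may be infeasible; the window is
then shifted minimally to fit the protein and the *realized* anchor is
recorded in the manifest (`requested_anchor` keeps the original request).
Shifting rather than shortening keeps peptide length — and therefore molar
comparability in pools — constant; peptides are shortened only when the
protein itself is shorter than $L$, in which case the `truncated` flag is
set. When both requested anchors collapse to the same shifted window the
window is emitted once. Alternative splice products are handled by supplying
each isoform as its own protein record; the designer does not model
splicing.

Minimal-epitope tiling enumerates *every* window of each requested length
(default 15 and 10) that contains the anchor residue: for a 20-mer anchored
at 15 that is 6 fifteen-mers (offsets 1–6) and 6 ten-mers (offsets 6–11).
Enumerating all windows, rather than a curated subset, makes the tile set
reproducible from the parent peptide alone; a screening lab can always
synthesize a subset.

```{r design}
wt <- paste(rep("A", 40), collapse = "")
mut <- applyMissense(wt, 20, "A", "Q")
peptideManifest(designLongPeptides(mut, wt, 20, "demo"))[, 1:8]
```

Tethered vaccine constructs join a helper (MHC II) epitope to an effector
(MHC I) epitope through a linker, triple alanine (`AAA`) by default — a
short, conformationally unobtrusive spacer that keeps both epitopes on one
molecule so a single antigen-presenting cell presents both.

## Pooled screening and deconvolution

Pools are built by a seeded shuffle followed by round-robin assignment, so
pool sizes differ by at most one and the layout is reproducible from the
seed (81 peptides in 16 pools gives one pool of 6 and fifteen of 5). The
screen is two-stage: pools are tested first against bulk lymphocytes; the
members of positive pools form the singleton retest list; singleton bulk
positives are then re-assayed with sorted CD4$^+$ and CD8$^+$ T cells for
subset attribution. A mutation's subset label is computed from arm-level
any-positive indicators: `dual` when both arms respond, `CD4_only` /
`CD8_only` when exactly one does. Sibling peptides of one mutation may land
in different pools (an optional `group_by` keeps them together); their
concordance in the hit table acts as an internal control.

## ELISPOT positivity

A stimulus condition with replicate well counts $x_1,\dots,x_n$ (spot-forming
cells, SFC) is compared with matched no-peptide control wells
$y_1,\dots,y_m$ and called positive only when **all four** criteria hold:

| criterion | statistic | threshold |
|---|---|---|
| count | $\bar{x}$ | $\ge 50$ SFC (inclusive) |
| significance | pooled-variance two-sample $t$, two-tailed | $p < 0.05$ (strict) |
| stimulation index | $\mathrm{SI} = \bar{x}/\bar{y}$ | $> 2$ (strict) |
| background | $P(X \ge \mathrm{round}(\bar{x}))$, $X \sim \mathrm{Pois}(\bar{y})$ | $< 0.05$ (strict) |

Numerical conventions: zero pooled variance gives $p = 1$ for equal means
and $p = 0$ otherwise (the limit of the $t$ tail); a zero control mean flags
the SI as infinite, and the SI criterion then passes iff any test signal
exists; a zero background rate gives Poisson tail 0 for positive counts and
1 otherwise. The Poisson criterion is formulated as an upper-tail
probability because ELISPOT well counts are conventionally treated as
Poisson — it asks whether background alone could plausibly have produced
the observed mean. The count criterion uses the raw (not
background-subtracted) test mean. The classic Student (pooled-variance)
test, not Welch, is used. Counts are assumed normalized to a shared
cells-per-well basis upstream; the module never rescales.

Under a null with test and control wells i.i.d. Poisson(60) and 3
replicates, the conjunction is extremely conservative — the SI and count
criteria alone exclude essentially all null conditions, and the measured
positive-call rate over $10^4$ trials is far below 0.05 (recomputed by both
the test suite and `scripts/acceptance.R`).

## Prediction audit

`screeningEfficiency()` takes functionally validated peptide ids and a
table of predicted IC50 affinities and reports the fraction a conventional
cutoff (500 nM, inclusive at the boundary) would have retained, truncated to
a whole percent (2 of 3 reports 66%) with the exact fraction alongside.
Truncation, not rounding, is used so a reported percentage never overstates
the cutoff's performance. One record per validated id is required;
aggregation over alleles or tile series (e.g. by minimum IC50) is left
upstream, where the choice of aggregate is visible.

## The synthetic-data generators

The generators exist to make every pipeline stage testable with known
truth; their defaults are the study conditions the package targets:

* `tier_counts = (4771, 1481, 270, 39)` — the variant cascade scale;
* `lambda_background = 10` SFC, `effect_multiplier = 15`,
  `n_replicates = 3` — strong immunogenic effect over a low background;
* `n_pools = 16`, anchors 6/15, 20-mers;
* `n_immunogenic = 4` of the 39 strict mutations, 1 dual-subset and the
  rest CD4-only.

Well counts are Poisson (matching the positivity rule's background model);
a negative-binomial option (`overdispersion`) exists for robustness testing
and is off by default. The immunogenic effect enters as a rate
*multiplier*, so the planted SI is directly readable from the config. A
pool containing at least one immunogenic member draws from the immunogenic
rate — pooling is assumed not to dilute a true response below detectability,
which is the practical rationale for pools of ~5 peptides.

Tier construction plants membership exactly: noncoding variants fill
`total − coding`; coding-but-unexpressed variants have `rna_alt = 0`;
expressed-but-not-strict variants alternate between the two failure modes
(fewer than 10 variant reads, or VAF below 20% with ≥10 reads, where depth
permits); strict variants draw depths from the upper part of the depth
range (≥50) so `rna_alt ≥ max(10, 0.2 · depth)` is always satisfiable. All
strict-tier variants are missense, so every strict variant is
design-eligible; other coding tiers mix in synonymous variants. RNA depths
of 3 replicate wells per condition follow common ELISPOT practice (the
per-condition replicate count is a fixture choice, not a biological
constant).

Determinism: every generator is a pure function of its config. A single
master seed is split into fixed per-generator streams (proteome 1, variants
2, pooled plate 3, singleton bulk plate 4, CD4 plate 5, CD8 plate 6,
immunogenic selection 7, pooling 8), so any intermediate can be regenerated
independently and regeneration is byte-identical. Generators save and
restore the caller's RNG state.

What the generator does *not* emulate: linkage between variants, realistic
codon/consequence structure, shared epitopes between mutations, antigen
abundance effects on spot counts, plate-position artifacts, or
between-animal variability. A passing end-to-end recovery therefore shows
the pipeline's logic and statistics are sound under its own model — not
that a wet-lab screen with these thresholds will reach the same sensitivity
on real lymphocytes.

## End to end

```{r e2e}
fx <- endToEndFixture(simulationConfig(seed = 42,
                                       tier_counts = c(120, 90, 60, 20),
                                       n_proteins = 12, n_pools = 8))
res <- runScreen(fx)
res$hits
hitsMatchTruth(res$hits, fx$truth$hits)
```

Under the default strong-effect conditions the screen recovers the planted
hit table — mutations, contributing peptides, and subset labels — in
essentially every seeded replicate, and a null configuration
(`effect_multiplier = 1`) yields zero hits because the count criterion
alone excludes background-level wells. `scripts/acceptance.R` recomputes
these rates (50 fixtures for recovery, $10^4$ trials for the null) along
with the cascade-recovery grid (problem sizes up to the full 4771-variant
cascade), the design oracle (1000 random proteins), and the worked IC50
audit; the whole script runs in about a minute on one CPU.

## Known limitations

* Only missense variants are designed automatically; indel/frameshift
  products must be supplied as precomputed mutant proteins (the anchor is
  then the first altered residue).
* One-dimensional pooling only (pool → singleton retest); matrix pooling
  designs are out of scope.
* The Poisson background criterion is one reasonable formalization of
  "Poisson < 5%" — conventions differ between labs, and the threshold
  arguments of `callPositive()` expose all four criteria for adjustment.
* The VCF importer expects consequence annotation in INFO keys and RNA
  counts in a companion table; it does not run a consequence predictor.
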