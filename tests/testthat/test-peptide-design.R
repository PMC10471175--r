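test_that("missense application substitutes exactly one residue", {
  expect_identical(applyMissense("ACDEF", 3, "D", "N"), "ACNEF")
  expect_error(applyMissense("ACDEF", 3, "E", "N"),
               "expected E, observed D")
  expect_error(applyMissense("ACDEF", 9, "D", "N"), "outside")
  set.seed(42)
  for (i in 1:25) {
    prot <- randomProtein(200)
    pos <- sample(200, 1)
    ref <- substr(prot, pos, pos)
    alt <- sample(setdiff(neoscreen:::AA_ALPHABET, ref), 1)
    mut <- applyMissense(prot, pos, ref, alt)
    diffs <- which(strsplit(prot, "")[[1]] != strsplit(mut, "")[[1]])
    expect_identical(diffs, as.integer(pos))
    expect_identical(substr(mut, pos, pos), alt)
  }
})

test_that("long-peptide windows place the mutation at the anchors", {
  wt <- randomProtein(40)
  mut <- applyMissense(wt, 20, substr(wt, 20, 20),
                       setdiff(neoscreen:::AA_ALPHABET,
                               substr(wt, 20, 20))[1])
  ps <- designLongPeptides(mut, wt, 20, "m1")
  man <- peptideManifest(ps)
  expect_equal(nrow(man), 4L)  # two anchors x (mutant, WT)
  m6 <- man[man$requested_anchor == 6 & man$is_mutant, ]
  m15 <- man[man$requested_anchor == 15 & man$is_mutant, ]
  expect_equal(m6$protein_start, 15L)   # residues 15-34
  expect_equal(m15$protein_start, 6L)   # residues 6-25
  expect_equal(m6$anchor, 6L)
  expect_equal(m15$anchor, 15L)
  # mutant/WT counterparts differ exactly at the anchor
  for (a in c(6, 15)) {
    mp <- man[man$requested_anchor == a & man$is_mutant, ]
    wp <- man[man$requested_anchor == a & !man$is_mutant, ]
    d <- which(strsplit(mp$sequence, "")[[1]] !=
                 strsplit(wp$sequence, "")[[1]])
    expect_identical(d, as.integer(mp$anchor))
  }
})

test_that("terminal windows shift minimally and record realized anchors", {
  wt <- randomProtein(40)
  # mutation near the N terminus: anchor-6 window clamps to 1-20
  mutN <- applyMissense(wt, 3, substr(wt, 3, 3), "W")
  manN <- peptideManifest(designLongPeptides(mutN, wt, 3, "mN"))
  a6 <- manN[manN$requested_anchor == 6 & manN$is_mutant, ]
  expect_equal(a6$protein_start, 1L)
  expect_equal(a6$anchor, 3L)
  # near the C terminus both anchor windows clamp to residues 21-40
  # and coincide, so a single mutant/WT pair is emitted
  mutC <- applyMissense(wt, 38, substr(wt, 38, 38), "W")
  manC <- peptideManifest(designLongPeptides(mutC, wt, 38, "mC"))
  aC <- manC[manC$is_mutant, ]
  expect_equal(nrow(aC), 1L)
  expect_equal(aC$protein_start, 21L)
  expect_equal(aC$anchor, 18L)
  # with only the anchor-15 window requested the same clamp applies
  a15 <- peptideManifest(designLongPeptides(mutC, wt, 38, "mC",
                                            anchors = 15L))
  expect_equal(a15$protein_start, c(21L, 21L))
  expect_equal(a15$anchor, c(18L, 18L))
  # both anchors infeasible: windows coincide and are emitted once
  mut1 <- applyMissense(wt, 1, substr(wt, 1, 1), "W")
  man1 <- peptideManifest(designLongPeptides(mut1, wt, 1, "m1"))
  expect_equal(nrow(man1), 2L)  # one window, mutant + WT
  expect_equal(unique(man1$protein_start), 1L)
  # protein shorter than the peptide: truncated with a warning
  shortp <- randomProtein(12)
  shortm <- applyMissense(shortp, 5, substr(shortp, 5, 5), "W")
  expect_warning(psS <- designLongPeptides(shortm, shortp, 5, "mS"),
                 "truncated")
  expect_true(all(peptideManifest(psS)$truncated))
  expect_true(all(nchar(peptideManifest(psS)$sequence) == 12L))
  expect_error(designLongPeptides(wt, wt, 99, "bad"), "outside")
  expect_error(designLongPeptides(wt, wt, 5, "bad", anchors = 25),
               "anchors")
})

test_that("random-case oracle: substring, anchor, single difference", {
  set.seed(7)
  for (i in 1:200) {
    len <- sample(21:200, 1)
    wt <- randomProtein(len)
    m <- sample(len, 1)
    ref <- substr(wt, m, m)
    alt <- sample(setdiff(neoscreen:::AA_ALPHABET, ref), 1)
    mut <- applyMissense(wt, m, ref, alt)
    man <- peptideManifest(designLongPeptides(mut, wt, m, "x"))
    for (j in seq_len(nrow(man))) {
      r <- man[j, ]
      src <- if (r$is_mutant) mut else wt
      expect_identical(substr(src, r$protein_start,
                              r$protein_start + nchar(r$sequence) - 1),
                       r$sequence)
      # mutated residue never leaves the peptide
      expect_true(r$protein_start <= m &&
                    m <= r$protein_start + nchar(r$sequence) - 1)
      expect_equal(r$anchor, m - r$protein_start + 1L)
      if (r$is_mutant)
        expect_identical(substr(r$sequence, r$anchor, r$anchor), alt)
    }
  }
})

test_that("tiling enumerates every window containing the anchor", {
  p <- PeptideSet(randomProtein(20), peptide_id = "Mut_t.a15",
                  mutation_id = "t", anchor = 15L, is_mutant = TRUE,
                  protein_start = 1L)
  t10 <- tileMinimalEpitopes(p, lengths = 10)
  expect_equal(nrow(t10), 6L)
  expect_equal(t10$offset, 6:11)
  # anchor at position 1: a single window
  p1 <- PeptideSet(randomProtein(20), peptide_id = "Mut_u.a1",
                   mutation_id = "u", anchor = 1L, is_mutant = TRUE,
                   protein_start = 1L)
  expect_equal(nrow(tileMinimalEpitopes(p1, lengths = 10)), 1L)
  expect_equal(tileMinimalEpitopes(p1, lengths = 10)$offset, 1L)
  # both default lengths: 6 fifteen-mers then 6 ten-mers
  tt <- tileMinimalEpitopes(p)
  expect_equal(nrow(tt), 12L)
  expect_equal(tt$length, rep(c(15L, 10L), each = 6))
  expect_equal(tt$tile_id, sprintf("Mut_t.a15.%d", 1:12))
  # sequences equal the parent substrings
  expect_identical(tt$sequence,
                   substring(as.character(p)[[1]], tt$offset,
                             tt$offset + tt$length - 1))
  expect_error(tileMinimalEpitopes(p, lengths = 25), "parent length")
})

test_that("tile offsets match brute-force enumeration for random anchors", {
  set.seed(13)
  for (i in 1:50) {
    plen <- sample(12:25, 1)
    k <- sample(plen, 1)
    L <- sample(8:min(plen, 16), 1)
    tiles <- tileMinimalEpitopes(randomProtein(plen), lengths = L,
                                 anchor = k, parent_id = "p")
    brute <- Filter(function(o) o <= k && k <= o + L - 1,
                    seq_len(plen - L + 1))
    expect_equal(tiles$offset, as.integer(brute))
  }
})

test_that("linked constructs concatenate helper, linker, effector", {
  lc <- buildLinkedConstruct("HHHHH", "EEEEE")
  expect_identical(combinedSequence(lc), "HHHHHAAAEEEEE")
  expect_identical(combinedSequence(buildLinkedConstruct("HHHHH", "EEEEE",
                                                         linker = "")),
                   "HHHHHEEEEE")
  expect_equal(nchar(combinedSequence(lc)), 5 + 3 + 5)
  expect_error(buildLinkedConstruct("", "EEEEE"), "non-empty")
  expect_error(buildLinkedConstruct("HHHHH", ""), "non-empty")
})

test_that("peptides round-trip through FASTA and manifest files", {
  wt <- randomProtein(60)
  mut <- applyMissense(wt, 30, substr(wt, 30, 30), "W")
  ps <- designLongPeptides(mut, wt, 30, "rt", gene_symbol = "G")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writePeptideFasta(ps, fa)
  back <- readPeptideFasta(fa)
  expect_identical(as.character(back), as.character(ps))
  expect_identical(peptideIds(back), peptideIds(ps))
  expect_equal(anchorPositions(back), anchorPositions(ps))
  expect_identical(isMutant(back), isMutant(ps))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writePeptideManifest(ps, tsv)
  expect_equal(readPeptideManifest(tsv)$sequence,
               peptideManifest(ps)$sequence)
})
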