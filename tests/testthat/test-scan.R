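r5_only <- function() r5Motifs(defaultMotifList())

test_that("overlapping motif occurrences are all reported", {
  ml <- EpitopeMotifList("r5_QQPFP", "QQPFP", "R5", "s")
  hits <- scanSequence("QPQQPFPQPQQPFPL", ml)
  expect_equal(hits$position, oracle_scan("QPQQPFPQPQQPFPL", "QQPFP"))
  expect_equal(hits$position, c(3L, 10L))
  expect_true(all(hits$intact))
  # overlapping repeat: QQQQPFP... style self-overlap
  h2 <- scanSequence("QQPFPQQPFPQQPFP", ml)
  expect_equal(h2$position, c(1L, 6L, 11L))
})

test_that("an immunogenic C-hordein peptide carries exactly one R5 motif", {
  hits <- scanSequence("IIPQQPQQPFPL", r5_only(), targetKind = "peptide")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$matched_span, "QQPFP")
  expect_equal(hits$position, 7L)
})

test_that("scanning handles empty results and bad inputs", {
  expect_equal(nrow(scanSequence("AAAAA", r5_only())), 0L)
  expect_error(scanSequence("AAAAA",
                            structure(list(), class = "data.frame")),
               class = "glutenscreen_config_error")
  # X never matches inside motifs
  expect_equal(nrow(scanSequence("QQPFX", r5_only())), 0L)
})

test_that("scanner agrees with the brute-force oracle on Q/P-rich strings", {
  set.seed(7)
  ml <- defaultMotifList()
  seqs <- motifSequences(ml)
  for (k in 1:60) {
    s <- random_qp_string(sample(20:200, 1))
    hits <- scanProteins(c(t1 = s), ml)
    for (id in names(seqs)) {
      got <- hits$position[hits$motif_id == id]
      expect_equal(got, oracle_scan(s, seqs[[id]]))
    }
  }
})

test_that("intact-core matching enforces the nine-residue criterion", {
  ml <- defaultMotifList()
  iedb <- ml["iedb_226653"]
  # peptide retains the full 13-mer region
  h <- intactCoreHits("QPQQPFPQPQQPFPL", iedb)
  expect_equal(nrow(h), 1L)
  expect_equal(nchar(h$matched_span), 13L)
  expect_true(h$intact)
  # a 5-mer R5 fragment cannot satisfy a 9-residue core
  dq <- ml[which(epitopeClasses(ml) == "DQ_core")[1]]
  expect_equal(nrow(intactCoreHits("QQPFP", dq)), 0L)
  # a peptide equal to the motif matches at position 1
  m <- motifSequences(dq)[[1]]
  h3 <- intactCoreHits(m, dq)
  expect_equal(h3$position, 1L)
  expect_true(h3$intact)
  # 8 of 9 residues retained is not enough
  h4 <- intactCoreHits(substr(m, 1, 8), dq)
  expect_equal(nrow(h4), 0L)
})

test_that("reported cores are the longest retained and match the oracle", {
  set.seed(8)
  ml <- defaultMotifList()
  long <- ml[which(nchar(motifSequences(ml)) >= 9)]
  seqs <- motifSequences(long)
  need <- minCoreMatch(long)
  for (k in 1:40) {
    p <- random_qp_string(sample(6:30, 1))
    h <- intactCoreHits(p, long)
    for (id in names(seqs)) {
      best <- oracle_longest_core(p, seqs[[id]])
      got <- h[h$motif_id == id, ]
      if (best >= need[[id]]) {
        expect_equal(nchar(got$matched_span), best)
      } else {
        expect_equal(nrow(got), 0L)
      }
    }
  }
})

test_that("peptide-level intact hits are consistent with the protein scan", {
  # any intact hit in a peptide cut from a protein corresponds to at least
  # a partial occurrence region of the motif in the protein
  set.seed(9)
  ml <- defaultMotifList()
  prot <- paste0(random_qp_string(40), "PQQPFPQPQQPFP", random_qp_string(40))
  for (k in 1:20) {
    a <- sample(1:80, 1); b <- min(nchar(prot), a + sample(8:25, 1))
    pep <- substr(prot, a, b)
    h <- intactCoreHits(pep, ml)
    if (nrow(h)) {
      for (span in h$matched_span)
        expect_true(grepl(span, prot, fixed = TRUE))
    }
  }
})

test_that("peptides are annotated with R5 and immunogenic status", {
  ann <- annotatePeptides(c("IIPQQPQQPFPL", "QPQQPFPQPQQPFPL", "AAAAA"))
  expect_equal(ann$r5_positive, c(TRUE, TRUE, FALSE))
  expect_equal(ann$immunogenic_positive, c(TRUE, TRUE, FALSE))
})
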