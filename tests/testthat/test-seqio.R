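write_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA headers parse into accession and description", {
  f <- write_fasta(c(">P06470 B1-hordein", "qqpfpqq*",
                     ">sp|Q41540|CM17 chloroform/methanol-soluble protein",
                     "MKVLAAF"))
  aa <- readProteinFasta(f)
  expect_equal(names(aa), c("P06470", "Q41540"))
  md <- S4Vectors::mcols(aa)
  expect_equal(md$description[1], "B1-hordein")
  # lowercase uppercased, '*' stripped
  expect_equal(as.character(aa[["P06470"]]), "QQPFPQQ")
})

test_that("malformed, empty and invalid FASTA inputs are reported", {
  bad <- write_fasta(c("", "ACGT", ">x", "AAA"))
  expect_error(readProteinFasta(bad), class = "glutenscreen_format_error")
  expect_error(readProteinFasta(bad), "line 2")

  empty <- write_fasta(character(0))
  expect_warning(aa <- readProteinFasta(empty), "empty")
  expect_length(aa, 0L)

  dup <- write_fasta(c(">a", "AAA", ">a", "CCC"))
  expect_error(readProteinFasta(dup), class = "glutenscreen_validation_error")

  badres <- write_fasta(c(">z1 odd", "AAB9"))
  expect_error(readProteinFasta(badres),
               class = "glutenscreen_validation_error")
})

test_that("annotations can be scalar or accession-named", {
  f <- write_fasta(c(">a", "AAA", ">b", "CCC"))
  aa <- readProteinFasta(f, proteinClass = c(a = "B-hordein", b = "ALP"))
  expect_equal(S4Vectors::mcols(aa)$protein_class, c("B-hordein", "ALP"))
  expect_error(readProteinFasta(f, proteinClass = "E-hordein"),
               class = "glutenscreen_validation_error")
})

test_that("peptide FASTA export round-trips with coordinate headers", {
  d <- inSilicoDigest(c(PROT1 = "MKDVSPGCRPITVSPGTRAAK"),
                      DigestParams("trypsin", maxMissedCleavages = 1,
                                   minLength = 3))
  f <- withr::local_tempfile(fileext = ".fasta")
  writePeptidesFasta(d, f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(length(back), nrow(d))
  expect_equal(as.character(back), d$sequence, ignore_attr = TRUE)
  hdr <- parsePeptideHeaders(names(back))
  expect_equal(hdr$start, d$start)
  expect_equal(hdr$end, d$end)
  expect_equal(hdr$missed_cleavages, d$missed_cleavages)
  expect_true(all(hdr$parent_accession == "PROT1"))
  # first peptide starts at residue 1
  expect_match(names(back)[1], "\\|1-")
  expect_error(writePeptidesFasta(d[0, ], f),
               class = "glutenscreen_validation_error")
})

test_that("peptide lists read from plain text or FASTA, deduplicated", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("IIPQQPQQPFPL", "aaaaa", "IIPQQPQQPFPL"), f)
  expect_equal(readPeptideList(f), c("IIPQQPQQPFPL", "AAAAA"))
  expect_length(readPeptideList(f, dedupe = FALSE), 3L)
  fa <- write_fasta(c(">p1", "QQPFP", ">p2", "LLLLL"))
  expect_equal(readPeptideList(fa), c("QQPFP", "LLLLL"))
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_warning(out <- readPeptideList(empty), "empty")
  expect_length(out, 0L)
})
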