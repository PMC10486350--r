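test_that("trypsin rule cleaves after K/R but not before proline", {
  p <- DigestParams("trypsin", maxMissedCleavages = 0, minLength = 1)
  d <- inSilicoDigest(c(x = "MKAAARPLK"), p)
  expect_equal(d$sequence, c("MK", "AAARPLK"))
  expect_equal(d$start, c(1L, 3L))
  expect_equal(d$end, c(2L, 9L))

  p1 <- DigestParams("trypsin", maxMissedCleavages = 1, minLength = 1)
  d1 <- inSilicoDigest(c(x = "MKAAARPLK"), p1)
  expect_true("MKAAARPLK" %in% d1$sequence)
  expect_setequal(d1$sequence, c("MK", "MKAAARPLK", "AAARPLK"))
})

test_that("chymotrypsin cleaves after F/W/Y/L/M with proline suppression", {
  p <- DigestParams("chymotrypsin", maxMissedCleavages = 0, minLength = 1)
  d <- inSilicoDigest(c(x = "GQGQQPGHGQQLAAF"), p)
  expect_equal(d$sequence, c("GQGQQPGHGQQL", "AAF"))
})

test_that("a wheat HMW-glutenin marker survives as one fully tryptic peptide", {
  # internal RP is not cleaved under the proline rule, so the peptide has
  # zero missed cleavages whenever its parent flanks are K/R-not-P
  parents <- c(a = "MKDVSPGCRPITVSPGTRAAK",
               b = "QQRDVSPGCRPITVSPGTRQQPL",
               c = "DVSPGCRPITVSPGTR")
  for (acc in names(parents)) {
    d <- inSilicoDigest(parents[acc],
                        DigestParams("trypsin", maxMissedCleavages = 0,
                                     minLength = 5))
    hit <- d[d$sequence == "DVSPGCRPITVSPGTR", ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$missed_cleavages, 0L)
  }
})

test_that("zero-missed-cleavage fragments concatenate to the parent", {
  set.seed(101)
  for (enz in c("trypsin", "chymotrypsin")) {
    for (k in 1:25) {
      s <- random_protein(sample(10:80, 1))
      p <- DigestParams(enz, maxMissedCleavages = 0, minLength = 1)
      d <- inSilicoDigest(c(x = s), p)
      expect_identical(paste(d$sequence[order(d$start)], collapse = ""), s)
    }
  }
})

test_that("each peptide spans exactly its recorded number of internal sites", {
  set.seed(102)
  p <- DigestParams("trypsin", maxMissedCleavages = 3, minLength = 1)
  for (k in 1:10) {
    s <- random_protein(60)
    sites <- cleavageSites(s, p)
    d <- inSilicoDigest(c(x = s), p)
    internal <- mapply(function(a, b) sum(sites >= a & sites < b),
                       d$start, d$end)
    expect_equal(unname(internal), d$missed_cleavages)
  }
})

test_that("digestion agrees with the brute-force substring oracle", {
  set.seed(103)
  for (k in 1:20) {
    s <- random_protein(sample(8:60, 1))
    enz <- sample(c("trypsin", "chymotrypsin"), 1)
    mc <- sample(0:2, 1)
    ml <- sample(1:4, 1)
    prl <- sample(c(TRUE, FALSE), 1)
    p <- DigestParams(enz, maxMissedCleavages = mc, minLength = ml,
                      prolineRule = prl)
    got <- inSilicoDigest(c(x = s), p)
    want <- oracle_digest(s, p@residues, prl, mc, ml)
    expect_equal(got[c("sequence", "start", "end", "missed_cleavages")],
                 want, ignore_attr = TRUE)
  }
})

test_that("disabling the proline rule never removes cleavage sites", {
  set.seed(104)
  for (k in 1:20) {
    s <- random_protein(50)
    on <- cleavageSites(s, DigestParams("trypsin"))
    off <- cleavageSites(s, DigestParams("trypsin", prolineRule = FALSE))
    expect_true(all(on %in% off))
    expect_gte(length(off), length(on))
  }
})

test_that("X is never a cleavage residue and parameters validate", {
  expect_equal(cleavageSites("AXAKA", DigestParams("trypsin")), 4L)
  expect_equal(cleavageSites("AXAXA",
                             DigestParams("chymotrypsin")), integer(0))
  expect_error(DigestParams("pepsin"), class = "glutenscreen_config_error")
  expect_error(DigestParams("trypsin", maxMissedCleavages = 9),
               "maxMissedCleavages")
  expect_error(DigestParams("trypsin", minLength = 0), "minLength")
})
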