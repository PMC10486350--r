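test_that("planted motif truth tables are exact against the test oracle", {
  plan <- c(QQPFP = 3)
  sim <- simulateProteins(5, plantPlan = plan, seed = 1)
  for (i in seq_along(sim$proteins)) {
    s <- as.character(sim$proteins[[i]])
    expect_length(oracle_scan(s, "QQPFP"), 3L)
  }
  expect_true(all(sim$truth$count == 3L))

  # nested plants: each 13-mer T-cell region contributes two R5 copies
  sim2 <- simulateProteins(3, plantPlan = c(QQPFP = 1, PQQPFPQPQQPFP = 1),
                           seed = 2)
  for (i in 1:3) {
    s <- as.character(sim2$proteins[[i]])
    expect_length(oracle_scan(s, "QQPFP"), 3L)  # 1 planted + 2 nested
    expect_length(oracle_scan(s, "PQQPFPQPQQPFP"), 1L)
  }
})

test_that("sequence simulation is seed-reproducible and handles edge sizes", {
  a <- simulateProteins(4, plantPlan = c(QQPFP = 1), seed = 9)
  b <- simulateProteins(4, plantPlan = c(QQPFP = 1), seed = 9)
  expect_identical(as.character(a$proteins), as.character(b$proteins))
  expect_identical(a$truth, b$truth)
  empty <- simulateProteins(0, seed = 1)
  expect_length(empty$proteins, 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(simulateProteins(1, lengthRange = c(8L, 9L),
                                plantPlan = c(PQQPFPQPQQPFP = 1), seed = 1),
               class = "glutenscreen_validation_error")
})

test_that("noise-free transition tables reproduce true abundances exactly", {
  peps <- data.frame(peptide_sequence = c("ELQESSLEACR", "AQQLAAMCR"),
                     true_abundance = c(1000, 250))
  sim <- simulateTransitions(peps, noiseSigma = 0, metOxFraction = 0.1,
                             seed = 3)
  q <- quantifyPeptides(readTransitionReport(sim$transitions))
  expect_equal(q$summed_area[q$peptide_sequence == "ELQESSLEACR"], 1000)
  # Met-containing peptide: oxidised + reduced forms merge conservatively
  expect_equal(q$summed_area[q$peptide_sequence == "AQQLAAMCR"], 250)
  expect_true(all(q$cv == 0))
  # the Met peptide really was split into two precursor forms
  mods <- unique(sim$transitions$modification[
    sim$transitions$peptide == "AQQLAAMCR"])
  expect_setequal(mods, c("reduced", "met_oxidised"))
})

test_that("replicate CVs under lognormal noise sit in the expected band", {
  set.seed(4)
  peps <- data.frame(peptide_sequence = sprintf("PEPTIDEQ%sR",
                                                strrep("A", 1:20)),
                     true_abundance = 10^seq(3, 5, length.out = 20))
  cvs <- c()
  for (seed in 1:5) {
    sim <- simulateTransitions(peps, noiseSigma = 0.1, seed = seed)
    q <- quantifyPeptides(readTransitionReport(sim$transitions))
    cvs <- c(cvs, q$cv)
  }
  expect_gte(mean(cvs >= 0.02 & cvs <= 0.25), 0.95)
})

test_that("dropouts remove rows but generated tables stay readable", {
  peps <- data.frame(peptide_sequence = "ELQESSLEACR",
                     true_abundance = 1000)
  sim <- simulateTransitions(peps, dropoutRate = 0.3, seed = 5)
  expect_lt(nrow(sim$transitions), 12L)
  expect_silent(quiet(readTransitionReport(sim$transitions)))
  expect_error(simulateTransitions(peps, transitionFractions = c(0.6, 0.6)),
               class = "glutenscreen_validation_error")
  expect_error(simulateTransitions(peps, dropoutRate = 1),
               class = "glutenscreen_validation_error")
  expect_error(simulateTransitions(peps, noiseSigma = -1),
               class = "glutenscreen_validation_error")
})

test_that("study bundles are coherent and reproducible", {
  b1 <- simulateStudy(seed = 12)
  b2 <- simulateStudy(seed = 12)
  expect_identical(b1$transitions, b2$transitions)
  expect_identical(b1$elisa, b2$elisa)
  expect_equal(nrow(b1$elisa), 14L)
  # every marker peptide has a class from its parent protein
  expect_true(all(b1$class_map %in%
                    c(hordeinClasses(), "ALP", "wheat-HMW-glutenin",
                      "other")))
  # without suppression the ELISA is a monotone function of net true
  # hordein signal, so concordance is perfect at truth level
  q <- quantifyPeptides(readTransitionReport(b1$transitions))
  s <- summariseClasses(q, b1$class_map)
  conc <- elisaConcordance(b1$elisa, s$net_hordein)
  expect_gt(conc$spearman, 0.9)

  # suppressing the ELISA signal of the three highest-signal samples must
  # surface them in the mismatch table: their MS rank stays near the top
  # while their ELISA rank collapses
  nt <- b1$net_true_hordein
  top3 <- nt$sample_id[order(-nt$net_true_area)][1:3]
  b3 <- simulateStudy(seed = 12,
                      suppression = setNames(rep(0.05, 3), top3))
  q3 <- quantifyPeptides(readTransitionReport(b3$transitions))
  s3 <- summariseClasses(q3, b3$class_map)
  conc3 <- elisaConcordance(b3$elisa, s3$net_hordein)
  expect_true(all(top3 %in% conc3$mismatches$sample_id))
})

test_that("log-abundance recovery bias stays within the sampling bound", {
  # bias of log(estimate) vs log(truth) < 3*sigma/sqrt(n_replicates)
  peps <- data.frame(peptide_sequence = sprintf("PEPTIDEQ%sR",
                                                strrep("L", 1:20)),
                     true_abundance = 10^seq(3, 5, length.out = 20))
  ok <- c()
  for (seed in 1:5) {
    sim <- simulateTransitions(peps, noiseSigma = 0.1, seed = seed)
    q <- quantifyPeptides(readTransitionReport(sim$transitions))
    tr <- merge(q, sim$truth, by.x = c("sample_id", "peptide_sequence"),
                by.y = c("sample_id", "peptide_sequence"))
    bias <- abs(log(tr$summed_area) - log(tr$true_abundance))
    ok <- c(ok, bias < 3 * 0.1 / sqrt(4))
  }
  expect_gte(mean(ok), 0.95)
})
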