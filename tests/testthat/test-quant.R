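make_meas <- function(df) readTransitionReport(df)

base_rows <- function(sample = "S1", rep = 1L, pep = "ELQESSLEACR",
                      mod = "none", areas = c(100, 200, 300)) {
  data.frame(sample = sample, replicate = rep, peptide = pep,
             modification = mod,
             transition = sprintf("t%d", seq_along(areas)), area = areas,
             stringsAsFactors = FALSE)
}

test_that("transition areas sum within replicates and merge Met forms", {
  m <- make_meas(base_rows())
  q <- quantifyPeptides(m)
  expect_equal(q$summed_area, 600)

  two_forms <- rbind(base_rows(mod = "reduced", areas = c(50, 50, 50)),
                     base_rows(mod = "met_oxidised", areas = c(10, 10, 10)))
  q2 <- quantifyPeptides(make_meas(two_forms))
  expect_equal(nrow(q2), 1L)   # one peptide, forms merged
  expect_equal(q2$summed_area, 180)
})

test_that("replicate means and CVs use the sample SD over replicate sums", {
  four <- do.call(rbind, lapply(1:4, function(r)
    base_rows(rep = r, areas = c(40, 30, 30))))
  q <- quantifyPeptides(make_meas(four))
  expect_equal(q$summed_area, 100)
  expect_equal(q$cv, 0)

  sums <- c(90, 100, 110, 100)
  var_hand <- sum((sums - mean(sums))^2) / (length(sums) - 1)
  cv_hand <- sqrt(var_hand) / mean(sums)        # = 0.08164966
  rows <- do.call(rbind, lapply(1:4, function(r)
    base_rows(rep = r, areas = c(sums[r] / 2, sums[r] / 4, sums[r] / 4))))
  q2 <- quantifyPeptides(make_meas(rows))
  expect_equal(q2$cv, cv_hand, tolerance = 1e-12)
  expect_equal(round(q2$cv, 4), 0.0816)
})

test_that("report parsing maps columns, drops missing areas, rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Sample,Replicate,Peptide,Transition,TotalArea",
               "S1,1,PEPTIDE,t1,100",
               "S1,1,PEPTIDE,t2,#N/A",
               "S1,1,PEPTIDE,t3,300"), f)
  m <- readTransitionReport(f, columnMap = c(area = "TotalArea"))
  expect_equal(nrow(m), 2L)     # missing area dropped, not zeroed
  expect_equal(sum(m$peak_area), 400)

  expect_error(readTransitionReport(data.frame(sample = "a", area = 1)),
               class = "glutenscreen_format_error")
  neg <- base_rows(areas = c(100, -5, 300))
  expect_error(readTransitionReport(neg), "row")
  dup <- rbind(base_rows(areas = 100), base_rows(areas = 200))
  expect_error(readTransitionReport(dup),
               class = "glutenscreen_validation_error")
})

test_that("peptides absent from some replicates are zero-filled and flagged", {
  rows <- rbind(base_rows(rep = 1L),
                base_rows(rep = 2L),
                base_rows(rep = 1L, pep = "LQPQQPR", areas = c(10, 10, 10)))
  q <- quiet(quantifyPeptides(make_meas(rows)))
  sparse <- q[q$peptide_sequence == "LQPQQPR", ]
  expect_equal(sparse$n_missing_replicates, 1L)
  expect_equal(sparse$summed_area, 15)   # (30 + 0) / 2
  full <- q[q$peptide_sequence == "ELQESSLEACR", ]
  expect_equal(full$n_missing_replicates, 0L)
})

test_that("quantitation is additive over row partitions and scale-equivariant", {
  set.seed(21)
  sim <- simulateTransitions(
    data.frame(peptide_sequence = c("ELQESSLEACR", "LQPQQPR", "AQQLAAMCR"),
               true_abundance = c(1000, 200, 5000)),
    noiseSigma = 0.2, seed = 21)
  m <- make_meas(sim$transitions)
  whole <- quantifyPeptides(m)
  parts <- lapply(split(m, m$transition_id), quantifyPeptides)
  merged <- Reduce(function(a, b) {
    stopifnot(identical(a$peptide_sequence, b$peptide_sequence))
    a$summed_area <- a$summed_area + b$summed_area
    a
  }, parts)
  expect_equal(merged$summed_area, whole$summed_area, tolerance = 1e-12)

  m2 <- m
  m2$peak_area <- m2$peak_area * 7
  q2 <- quantifyPeptides(m2)
  expect_equal(q2$summed_area, whole$summed_area * 7, tolerance = 1e-12)
  expect_equal(q2$cv, whole$cv, tolerance = 1e-12)
})

test_that("class summaries aggregate peptides and exclude ALPs from net hordein", {
  q <- data.frame(sample_id = "S1",
                  peptide_sequence = c("GAMMA1", "GAMMA2", "ALPPEP", "BPEP"),
                  summed_area = c(10, 30, 1000, 5),
                  cv = 0, n_replicates = 4L, n_missing_replicates = 0L,
                  detected = TRUE, stringsAsFactors = FALSE)
  cmap <- c(GAMMA1 = "gamma-hordein", GAMMA2 = "gamma-hordein",
            ALPPEP = "ALP", BPEP = "B-hordein")
  s <- summariseClasses(q, cmap)
  g <- s$classes[s$classes$protein_class == "gamma-hordein", ]
  expect_equal(g$net_area, 40)
  expect_equal(g$mean_area, 20)
  expect_equal(s$net_hordein$net_area, 45)  # ALP excluded

  # net hordein equals the sum of the four hordein class nets
  hc <- s$classes[s$classes$protein_class %in% hordeinClasses(), ]
  expect_equal(sum(hc$net_area), s$net_hordein$net_area)

  expect_warning(s2 <- summariseClasses(q, cmap[-1]), "class map")
  expect_equal(attr(s2, "unmapped"), "GAMMA1")

  # a sample with no hordein peptides reports net 0
  q3 <- q[q$peptide_sequence == "ALPPEP", ]
  s3 <- summariseClasses(q3, cmap)
  expect_equal(s3$net_hordein$net_area, 0)
})
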