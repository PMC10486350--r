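# Independent naive occurrence counter used to verify planted motifs. This
# deliberately does not share code with the production scanner
# (Biostrings::matchPattern) so plant verification is not circular.
naiveCountOccurrences <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(sequence, i, i + m - 1L) == motif,
             logical(1)))
}

# Default Q/P-rich background residue weights emulating prolamin composition.
defaultBackgroundWeights <- function() {
  c(Q = 30, P = 18, F = 4, L = 7, S = 5, V = 4, I = 3, A = 4, G = 4,
    E = 3, R = 3, K = 2, T = 3, N = 2, Y = 2, H = 2, C = 2, W = 1,
    M = 2, D = 2)
}

#' Simulate prolamin-like proteins with planted epitopes
#'
#' Generates repetitive Q/P-rich protein sequences of the kind typical of
#' prolamin storage proteins: sampled short repeat units separated by short
#' runs of weighted background residues, with epitope motifs planted at
#' random positions. Generation is verified with an independent naive
#' scanner (not the production scanner): accidental occurrences of planted
#' motifs in the repetitive background are scrubbed by single-residue
#' mutation until the background is clean, each insertion point is redrawn
#' until it
#' creates no boundary artefacts, and the final occurrence count of every
#' planted motif equals its expected count -- the planted number plus
#' occurrences nested inside other planted motifs (e.g. each planted
#' PQQPFPQPQQPFP contains QQPFP twice). The returned truth table records
#' these verified exact counts.
#'
#' @param nProteins number of proteins (0 gives an empty set).
#' @param lengthRange integer pair, background length range before
#'   insertion.
#' @param repeatUnits pool of short Q/P-rich repeat units. Units that
#'   contain a planted motif are dropped from the pool (they would make
#'   exact planted counts unreachable).
#' @param plantPlan named numeric: motif sequence -> planted occurrences
#'   per protein (applied to every protein). \code{NULL} plants nothing.
#' @param backgroundWeights named residue weights for background positions.
#' @param classPool protein classes cycled across proteins.
#' @param seed integer seed; identical seeds give identical output.
#' @param retryLimit redraws allowed per protein before failing with advice
#'   to lower the plant density.
#' @return list with \code{proteins} (an \code{AAStringSet} with
#'   \code{protein_class} metadata, accessions \code{SIM0001}...) and
#'   \code{truth} (data.frame \code{accession}, \code{motif},
#'   \code{count}).
#' @export
#' @examples
#' sim <- simulateProteins(3, plantPlan = c(QQPFP = 2), seed = 1)
#' sim$truth
simulateProteins <- function(nProteins, lengthRange = c(150L, 400L),
                             repeatUnits = c("PQQP", "QQPFP", "QPQQ", "PFPQ"),
                             plantPlan = NULL,
                             backgroundWeights = defaultBackgroundWeights(),
                             classPool = c(HORDEIN_CLASSES, "ALP"),
                             seed = NULL, retryLimit = 50L) {
  if (nProteins < 0) gs_validation_error("nProteins must be >= 0")
  if (any(backgroundWeights <= 0))
    gs_validation_error("background weights must be positive")
  if (!is.null(plantPlan)) {
    if (is.null(names(plantPlan)))
      gs_validation_error("plantPlan must be named by motif sequence")
    names(plantPlan) <- toupper(names(plantPlan))
    checkAASequences(names(plantPlan), ids = names(plantPlan),
                     allow_x = FALSE, what = "planted motif")
    if (any(nchar(names(plantPlan)) > min(lengthRange)))
      gs_validation_error("planted motif longer than minimum protein length")
    repeatUnits <- repeatUnits[!vapply(repeatUnits, function(u)
      any(vapply(names(plantPlan), function(m)
        grepl(m, u, fixed = TRUE), logical(1))), logical(1))]
    if (!length(repeatUnits)) repeatUnits <- NULL
  }
  if (!is.null(seed)) set.seed(seed)
  motifs <- names(plantPlan)
  # Expected count of motif m per protein: its own plants plus nested
  # occurrences inside every other planted motif.
  expected <- if (length(motifs)) vapply(motifs, function(m)
    sum(vapply(motifs, function(m2)
      if (m2 == m) plantPlan[[m]]
      else plantPlan[[m2]] * naiveCountOccurrences(m2, m), numeric(1))),
    numeric(1)) else numeric(0)

  residues <- names(backgroundWeights)
  probs <- backgroundWeights / sum(backgroundWeights)
  drawBackground <- function(len) {
    out <- character(0)
    while (sum(nchar(out)) < len) {
      if (!is.null(repeatUnits))
        out <- c(out, sample(repeatUnits, 1L))
      out <- c(out, paste(sample(residues, sample(1:4, 1L), replace = TRUE,
                                 prob = probs), collapse = ""))
    }
    substr(paste(out, collapse = ""), 1L, len)
  }
  countAll <- function(s) vapply(motifs, function(m)
    naiveCountOccurrences(s, m), numeric(1))

  # Stage 1: a background free of any planted motif. Prolamin-like repeat
  # text spontaneously spells epitope motifs, so accidental occurrences are
  # scrubbed by mutating one internal residue (to a neutral non-Q/P letter)
  # rather than redrawing whole sequences; re-scanned until clean.
  scrub_letters <- c("S", "A", "G", "T", "V")
  drawCleanBackground <- function(len) {
    bg <- drawBackground(len)
    if (!length(motifs)) return(bg)
    for (try in seq_len(retryLimit * 10L)) {
      counts <- countAll(bg)
      if (all(counts == 0)) return(bg)
      m <- motifs[which(counts > 0)[1]]
      pos <- regexpr(m, bg, fixed = TRUE)
      mid <- pos + nchar(m) %/% 2L
      substr(bg, mid, mid) <- sample(scrub_letters, 1L)
    }
    gs_stop("glutenscreen_generation_error",
            "could not scrub background motif occurrences in %d passes; lower the background repeat content",
            retryLimit * 10L)
  }
  # Stage 2: insert each plant at a random cut, accepting the cut only if
  # the realised counts advance by exactly the inserted motif and its
  # nested occurrences (no boundary-created extras).
  plantInto <- function(bg) {
    inserts <- sample(rep(motifs, times = plantPlan[motifs]))
    s <- bg
    target <- countAll(s)
    for (ins in inserts) {
      target <- target + vapply(motifs, function(m)
        if (m == ins) max(1, naiveCountOccurrences(ins, m))
        else naiveCountOccurrences(ins, m), numeric(1))
      placed <- FALSE
      for (try in seq_len(retryLimit)) {
        cut <- sample(0:nchar(s), 1L)
        cand <- paste0(substr(s, 1L, cut), ins,
                       substr(s, cut + 1L, nchar(s)))
        if (all(countAll(cand) == target)) {
          s <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        gs_stop("glutenscreen_generation_error",
                "could not place planted motif %s without side effects in %d tries; lower the plant density",
                ins, retryLimit)
    }
    s
  }

  seqs <- character(nProteins)
  truth <- vector("list", nProteins)
  for (i in seq_len(nProteins)) {
    len <- sample(lengthRange[1]:lengthRange[2], 1L)
    s <- drawCleanBackground(len)
    if (length(motifs)) {
      s <- plantInto(s)
      stopifnot(all(countAll(s) == expected[motifs]))
    }
    seqs[i] <- s
    truth[[i]] <- if (length(motifs))
      data.frame(accession = sprintf("SIM%04d", i), motif = motifs,
                 count = as.integer(expected[motifs]),
                 stringsAsFactors = FALSE)
    else NULL
  }
  accs <- sprintf("SIM%04d", seq_len(nProteins))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- accs
  S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
    accession = accs,
    description = rep("simulated prolamin-like protein", nProteins),
    protein_class = if (nProteins) rep_len(classPool, nProteins)
                    else character(0),
    species_tag = rep("barley", nProteins))
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(accession = character(0), motif = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  list(proteins = aa, truth = truth)
}

#' Simulate an MRM transition table with known true abundances
#'
#' Emulates the structure of a targeted MRM export: per (sample, replicate,
#' peptide, transition) peak areas with \code{area = true_abundance *
#' sample_scale * transition_fraction * mod_split * exp(N(0, sigma^2))},
#' multiplicative lognormal noise being the standard model for MS
#' intensities. Met-containing peptides are split between reduced and
#' oxidised precursor forms; dropouts remove individual transition rows.
#'
#' @param peptides data.frame with columns \code{peptide_sequence},
#'   \code{true_abundance}.
#' @param sampleIds sample identifiers (default one sample \code{"S1"}).
#' @param sampleScale named per-sample abundance multipliers (default 1).
#' @param nReplicates technical replicates per sample (default 4).
#' @param transitionFractions per-transition share of the peptide signal;
#'   must sum to 1 (default \code{c(0.5, 0.3, 0.2)}).
#' @param metOxFraction fraction of a Met-containing peptide's signal in
#'   the oxidised form, in [0, 1) (default 0.1).
#' @param noiseSigma lognormal sigma (>= 0).
#' @param dropoutRate probability that a transition row is missing, in
#'   [0, 1).
#' @param seed integer seed.
#' @return list with \code{transitions} (data.frame with columns
#'   \code{sample}, \code{replicate}, \code{peptide}, \code{modification},
#'   \code{transition}, \code{area}, directly consumable by
#'   \code{\link{readTransitionReport}}) and \code{truth} (data.frame
#'   \code{sample_id}, \code{peptide_sequence}, \code{true_abundance},
#'   scale applied).
#' @export
#' @examples
#' sim <- simulateTransitions(
#'   data.frame(peptide_sequence = "ELQESSLEACR", true_abundance = 1000),
#'   noiseSigma = 0, seed = 1)
#' sum(sim$transitions$area)  # 4 replicates x 1000
simulateTransitions <- function(peptides, sampleIds = "S1",
                                sampleScale = NULL, nReplicates = 4L,
                                transitionFractions = c(0.5, 0.3, 0.2),
                                metOxFraction = 0.1, noiseSigma = 0.1,
                                dropoutRate = 0, seed = NULL) {
  if (abs(sum(transitionFractions) - 1) > 1e-9)
    gs_validation_error("transition fractions must sum to 1")
  if (noiseSigma < 0) gs_validation_error("noiseSigma must be >= 0")
  if (dropoutRate < 0 || dropoutRate >= 1)
    gs_validation_error("dropoutRate must be in [0, 1)")
  if (metOxFraction < 0 || metOxFraction >= 1)
    gs_validation_error("metOxFraction must be in [0, 1)")
  if (is.null(sampleScale))
    sampleScale <- setNames(rep(1, length(sampleIds)), sampleIds)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(transitionFractions)
  rows <- list()
  truth <- list()
  for (s in sampleIds) {
    scale <- sampleScale[[s]]
    truth[[s]] <- data.frame(sample_id = s,
                             peptide_sequence = peptides$peptide_sequence,
                             true_abundance = peptides$true_abundance * scale,
                             stringsAsFactors = FALSE)
    for (r in seq_len(nReplicates)) {
      for (p in seq_len(nrow(peptides))) {
        pep <- peptides$peptide_sequence[p]
        base <- peptides$true_abundance[p] * scale
        mods <- if (grepl("M", pep, fixed = TRUE) && metOxFraction > 0)
          c(reduced = 1 - metOxFraction, met_oxidised = metOxFraction)
        else c(none = 1)
        for (mi in seq_along(mods)) {
          for (t in seq_len(nt)) {
            if (dropoutRate > 0 && stats::runif(1) < dropoutRate) next
            area <- base * mods[[mi]] * transitionFractions[t] *
              exp(stats::rnorm(1, 0, noiseSigma))
            rows[[length(rows) + 1L]] <- list(
              sample = s, replicate = r, peptide = pep,
              modification = names(mods)[mi],
              transition = sprintf("t%d", t), area = area)
          }
        }
      }
    }
  }
  transitions <- if (length(rows))
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  else data.frame(sample = character(0), replicate = integer(0),
                  peptide = character(0), modification = character(0),
                  transition = character(0), area = numeric(0),
                  stringsAsFactors = FALSE)
  rownames(transitions) <- NULL
  list(transitions = transitions, truth = do.call(rbind, c(truth,
       list(make.row.names = FALSE))))
}

#' Simulate a complete screening study
#'
#' End-to-end synthetic input bundle mirroring a beer-survey design:
#' prolamin-like proteins with planted epitopes are digested in silico,
#' marker peptides are chosen, per-sample transition tables with known true
#' abundances are generated, and ELISA-like values are derived as a
#' monotone (linear) function of each sample's true net hordein abundance.
#' Optional per-sample \code{suppression} factors (< 1) scale the ELISA
#' value down without touching the MS signal, emulating the
#' ELISA-versus-LC-MS mismatch seen when antibody signals are suppressed in
#' hydrolysed samples.
#'
#' @param nProteins simulated proteins (default 12).
#' @param nControl,nLowGluten numbers of control / low-gluten samples
#'   (default 5 and 9, the survey design; low-gluten samples draw smaller
#'   abundance scale factors).
#' @param peptidesPerProtein marker peptides retained per protein
#'   (default 2).
#' @param plantPlan planted motifs per protein (default one QQPFP).
#' @param digestParams a \linkS4class{DigestParams} (default trypsin,
#'   2 missed cleavages, length >= 7 for marker suitability).
#' @param noiseSigma,nReplicates,transitionFractions,metOxFraction,dropoutRate
#'   passed to \code{\link{simulateTransitions}}.
#' @param suppression named numeric of per-sample ELISA suppression factors
#'   in (0, 1]; default none.
#' @param elisaScalePerArea mg/kg of ELISA signal per unit of true net
#'   hordein area (default chosen to give control beers tens of mg/kg).
#' @param seed integer seed.
#' @return list with elements \code{proteins}, \code{truth_motifs},
#'   \code{peptides} (digest table of the chosen markers),
#'   \code{class_map}, \code{transitions}, \code{truth_abundance},
#'   \code{net_true_hordein}, \code{elisa}, \code{suppression}.
#' @export
simulateStudy <- function(nProteins = 12L, nControl = 5L, nLowGluten = 9L,
                          peptidesPerProtein = 2L,
                          plantPlan = c(QQPFP = 1),
                          digestParams = DigestParams("trypsin",
                                                      minLength = 7L),
                          noiseSigma = 0.1, nReplicates = 4L,
                          transitionFractions = c(0.5, 0.3, 0.2),
                          metOxFraction = 0.1, dropoutRate = 0,
                          suppression = NULL,
                          elisaScalePerArea = 2e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulateProteins(nProteins, lengthRange = c(120L, 260L),
                          plantPlan = plantPlan, seed = NULL)
  digest <- inSilicoDigest(sim$proteins, digestParams)
  digest <- digest[digest$missed_cleavages == 0L &
                     nchar(digest$sequence) <= 25L, , drop = FALSE]
  pick <- do.call(rbind, lapply(split(digest, digest$parent_accession),
                                function(g)
    utils::head(g[order(g$start), , drop = FALSE], peptidesPerProtein)))
  pick <- pick[!duplicated(pick$sequence), , drop = FALSE]
  rownames(pick) <- NULL
  if (!nrow(pick))
    gs_stop("glutenscreen_generation_error",
            "digestion produced no usable marker peptides; widen lengthRange or relax digestParams")
  cls <- setNames(S4Vectors::mcols(sim$proteins)$protein_class,
                  names(sim$proteins))
  class_map <- setNames(unname(cls[pick$parent_accession]), pick$sequence)

  samples <- c(sprintf("C%d", seq_len(nControl)),
               sprintf("LG%d", seq_len(nLowGluten)))
  scale <- setNames(c(exp(stats::rnorm(nControl, 0, 0.4)),
                      0.15 * exp(stats::rnorm(nLowGluten, 0, 0.6))),
                    samples)
  peptides <- data.frame(peptide_sequence = pick$sequence,
                         true_abundance = 10^stats::runif(nrow(pick), 3, 5),
                         stringsAsFactors = FALSE)
  tsim <- simulateTransitions(peptides, sampleIds = samples,
                              sampleScale = scale,
                              nReplicates = nReplicates,
                              transitionFractions = transitionFractions,
                              metOxFraction = metOxFraction,
                              noiseSigma = noiseSigma,
                              dropoutRate = dropoutRate, seed = NULL)
  truth <- tsim$truth
  truth$protein_class <- unname(class_map[truth$peptide_sequence])
  hord <- truth[truth$protein_class %in% HORDEIN_CLASSES, , drop = FALSE]
  net_true <- stats::aggregate(true_abundance ~ sample_id, data = hord,
                               FUN = sum)
  names(net_true)[2] <- "net_true_area"
  supp <- setNames(rep(1, length(samples)), samples)
  if (!is.null(suppression)) {
    unknown <- setdiff(names(suppression), samples)
    if (length(unknown))
      gs_validation_error("suppression names unknown sample(s): %s",
                          paste(unknown, collapse = ", "))
    supp[names(suppression)] <- suppression
  }
  elisa <- data.frame(
    sample_id = net_true$sample_id,
    gluten_mg_per_kg = elisaScalePerArea * net_true$net_true_area *
      unname(supp[net_true$sample_id]),
    label_group = ifelse(grepl("^LG", net_true$sample_id), "low_gluten",
                         "control"),
    stringsAsFactors = FALSE)
  list(proteins = sim$proteins, truth_motifs = sim$truth, peptides = pick,
       class_map = class_map, transitions = tsim$transitions,
       truth_abundance = truth, net_true_hordein = net_true, elisa = elisa,
       suppression = supp)
}
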