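table2 <- readTraitTable(system.file("extdata", "vertebrate_species.tsv",
                                     package = "thermaa"))

test_that("prokaryote pipeline recovers an imposed composition-temperature link", {
  cfg <- generatorConfig(nSpecies = 30, proteinsPerSpecies = 40,
                         lengthRange = c(150, 300), beta = 0.05, seed = 101)
  panel <- simulateSpeciesPanel(cfg)
  rep <- runProkaryoteAnalysis(panel$proteomes, panel$traits,
                               tree = panel$tree, nPerm = 499, seed = 1)
  expect_gt(unname(testStatistic(rep$naive$pearson)), 0)
  expect_gt(rep$comparative$R, 0)
  expect_equal(nrow(rep$perAminoAcid), 20)
  expect_true(all(c("R", "p", "RComp", "pComp") %in% names(rep$perAminoAcid)))
  expect_equal(nrow(rep$speciesStats), 30)
  ## species ERK tracks the generator's expectation (~9000 residues/species
  ## puts the composition sampling noise near 0.8 pp, about the size of the
  ## imposed signal, so the correlation is clear but not near 1)
  expect_gt(cor(rep$speciesStats$ERK, panel$expectedErk[rep$speciesStats$species]),
            0.5)
})

test_that("end-to-end recovery: positive contrast correlation across seeds", {
  ## full generator -> pipeline chain at the default proteome scale: the
  ## imposed 0.05 pp/degC slope must surface as positive naive and contrast
  ## correlations with a significant randomization p in most seeds
  hits <- vapply(1:5, function(s) {
    panel <- simulateSpeciesPanel(generatorConfig(seed = s * 13))
    erks <- vapply(panel$proteomes, function(p)
      unname(proteomeBias(p, "ERK")$concatenated["ERK"]), numeric(1))
    cE <- independentContrasts(panel$tree, erks)
    cT <- independentContrasts(panel$tree,
                               setNames(panel$traits$temperature,
                                        panel$traits$species))
    naive <- cor(erks, panel$traits$temperature)
    r <- contrastCorrelation(cE, cT)
    p <- pValue(randomizationPvalue(cE, cT, nPerm = 999, seed = s))
    naive > 0 && r > 0 && p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("prokaryote pipeline degrades gracefully and validates input", {
  cfg <- generatorConfig(nSpecies = 6, proteinsPerSpecies = 5,
                         sigma2 = 0.5, rootTemperature = 30, seed = 7)
  panel <- simulateSpeciesPanel(cfg)   # tight around 30 C: all mesophiles
  rep <- runProkaryoteAnalysis(panel$proteomes, panel$traits)
  expect_length(rep$groupTests, 0)
  expect_true(any(grepl("group", rep$notes)))
  expect_true(any(grepl("tree", rep$notes)))
  expect_null(rep$comparative)
  expect_true(all(is.na(rep$perAminoAcid$RComp)))
  expect_true(all(is.finite(rep$perAminoAcid$R) | is.na(rep$perAminoAcid$R)))

  badTraits <- panel$traits
  badTraits$species[1] <- "someone_else"
  expect_error(runProkaryoteAnalysis(panel$proteomes, badTraits), "mismatch")
})

test_that("vertebrate pipeline on a published-style species table", {
  rep <- runVertebrateAnalysis(traits = table2)
  expect_equal(pValue(rep$groupTests$ERK), 0.0075, tolerance = 0.01)
  expect_equal(pValue(rep$groupTests$temperature), 0.0080, tolerance = 0.01)
  expect_equal(nrow(rep$speciesTable), 11)

  oneGroup <- table2[table2$group == "ectotherm", ]
  expect_error(runVertebrateAnalysis(traits = oneGroup), "both endotherm")
})

test_that("vertebrate pipeline runs orthology, contrasts and codon controls", {
  cfg <- generatorConfig(nSpecies = 5, lengthRange = c(60, 100),
                         substitutionRate = 0.05, seed = 55,
                         rootTemperature = 30, sigma2 = 40)
  pan <- simulateOrthologPanel(cfg, nGenes = 12)
  traits <- data.frame(species = names(pan$proteomes),
                       temperature = unname(pan$temperatures),
                       group = c("endotherm", "endotherm", "ectotherm",
                                 "ectotherm", "ectotherm"),
                       stringsAsFactors = FALSE)
  rep <- runVertebrateAnalysis(traits = traits, proteomes = pan$proteomes,
                               tree = pan$tree, cds = pan$cds,
                               hitTables = pan$hitTables, reference = "s3",
                               matchedPair = c("s1", "s3"),
                               nPerm = 199, seed = 3)
  expect_equal(rep$orthology$nGroups, 12)   # full recovery at low divergence
  expect_equal(nrow(rep$orthology$perSpeciesTests), 4)
  expect_true(is(rep$comparative$randomization, "RandomizationResult"))
  expect_true(all(c("pct_at_rich", "pct_gc_rich") %in% names(rep$speciesTable)))
  expect_gt(rep$matchedControls$gc_neutral$nGenes, 0)
  expect_true(is.finite(rep$matchedControls$gc_neutral$pairedWilcoxonP))
  expect_true(is.finite(rep$matchedControls$purine_neutral$pairedWilcoxonP))

  expect_error(
    runVertebrateAnalysis(traits = traits, proteomes = pan$proteomes,
                          hitTables = pan$hitTables, reference = "nope"),
    "reference species")
})

test_that("segment comparison tests each labeled pair set", {
  ## identical sides: p = 1
  same <- data.frame(label = "self", segA = c("MERKDD", "LLVKEE"),
                     segB = c("MERKDD", "LLVKEE"), stringsAsFactors = FALSE)
  expect_equal(runSegmentComparison(same)$p, 1)

  ## one side shifted up by ~1 pp ERK across many segments: detected
  set.seed(61)
  n <- 500
  segB <- vapply(rep(100, n), randomProtein, character(1))
  segA <- vapply(segB, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(ch %in% c("D", "N", "Q", "T", "S", "H", "A"))
    flip <- head(idx, 1)      # one depleted residue becomes E: +2 pp
    if (length(flip)) ch[flip] <- "E"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  shifted <- data.frame(label = "shift", segA = segA, segB = segB,
                        stringsAsFactors = FALSE)
  expect_lt(runSegmentComparison(shifted)$p, 0.01)

  ## mixed labels: one row per label, aligned gaps stripped
  mixed <- rbind(same, data.frame(label = "gapped", segA = "ME-RK",
                                  segB = "MEDRK", stringsAsFactors = FALSE))
  out <- runSegmentComparison(mixed)
  expect_equal(sort(out$label), c("gapped", "self"))

  expect_error(runSegmentComparison(same[0, ]), "empty")
})
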